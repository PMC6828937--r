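## Per-field summaries: cell-area normalization, nuclei counting,
## two-marker colocalization and the Table-style metric row.

#' Segment the cell-covered region of a field
#'
#' Low-threshold segmentation of the diffuse cytoplasmic signal: the
#' maximum projection over the non-DAPI channels is mildly blurred,
#' thresholded at a low fixed constant, morphologically closed and
#' hole-filled. The returned fraction (mask pixels / field pixels) is
#' used to normalize particle counts to a fully covered field.
#'
#' @param images list of \linkS4class{FieldImage} (or matrices); DAPI
#'   channels are ignored.
#' @param blurSigmaPx blur applied before thresholding.
#' @param threshold fixed low threshold (8-bit counts).
#' @param closeSizePx diameter of the disc brush used for closing.
#' @return List with \code{mask} (logical matrix) and \code{fraction};
#'   a fraction below 1\% triggers a warning (blank field).
#' @export
cellMask <- function(images, blurSigmaPx = 2, threshold = 8,
                     closeSizePx = 7) {
  if (is(images, "FieldImage") || is.matrix(images)) images <- list(images)
  mats <- lapply(images, function(im) {
    if (is(im, "FieldImage")) {
      if (im@channel == "dapi") NULL else im@pixels
    } else im
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) stop("no cytoplasmic channel supplied")
  proj <- Reduce(pmax, mats)
  sm <- gaussianBlur(proj, blurSigmaPx)
  mask <- sm >= threshold
  eb <- EBImage::Image(mask * 1)
  eb <- EBImage::closing(eb, EBImage::makeBrush(closeSizePx, "disc"))
  eb <- EBImage::fillHull(eb)
  mask <- EBImage::imageData(eb) > 0.5
  fraction <- mean(mask)
  if (fraction < 0.01)
    warning("cell-covered fraction is ~0; field appears blank")
  list(mask = mask, fraction = fraction)
}

#' Normalize a particle count to full cell coverage
#'
#' Divides the raw per-field count by the cell-covered area fraction,
#' i.e. reports the count expected if the field were completely covered
#' with cells.
#'
#' @param pbCountRaw raw particle count.
#' @param cellAreaFraction fraction in (0, 1].
#' @return Normalized count.
#' @examples
#' normalizeCount(100, 0.5)  # 200
#' @export
normalizeCount <- function(pbCountRaw, cellAreaFraction) {
  if (!is.finite(cellAreaFraction) || cellAreaFraction <= 0)
    stop("cellAreaFraction must be > 0 (no cells in field?)")
  if (cellAreaFraction > 1) stop("cellAreaFraction must be <= 1")
  pbCountRaw / cellAreaFraction
}

#' Count nuclei in the DAPI channel
#'
#' Blur, automatic (Otsu) threshold, hole filling, 8-connectivity
#' labeling, and rejection of components smaller than
#' \code{minAreaPx2}. Touching nuclei are not split (counts, not
#' shapes, are the target); the size floor suppresses debris.
#'
#' @param dapi \linkS4class{FieldImage} or matrix of the DAPI channel.
#' @param blurSigmaPx blur before thresholding.
#' @param minAreaPx2 minimum component area retained (default 2000 px^2,
#'   about a 4.6 um diameter disk at 102.33 nm/px).
#' @return Integer nuclei count.
#' @export
countNuclei <- function(dapi, blurSigmaPx = 2, minAreaPx2 = 2000) {
  if (is(dapi, "FieldImage") && dapi@channel != "dapi")
    stop("countNuclei expects the DAPI channel")
  m <- if (is(dapi, "FieldImage")) dapi@pixels else dapi
  sm <- gaussianBlur(m, blurSigmaPx) / 255
  if (max(sm) - min(sm) < 1e-8) return(0L)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > thr
  eb <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- EBImage::imageData(eb) > 0.5
  labels <- labelParticles(mask)
  if (max(labels) == 0L) return(0L)
  areas <- tabulate(labels[labels > 0L], nbins = max(labels))
  sum(areas >= minAreaPx2)
}

#' Particles per cell
#'
#' Ratio of the raw particle count to the nuclei count of the same
#' field; \code{NA} when no nuclei were found.
#'
#' @param pbCountRaw raw particle count.
#' @param nucleiCount nuclei count.
#' @return Count per cell, or \code{NA_real_} if \code{nucleiCount < 1}.
#' @export
pbPerCell <- function(pbCountRaw, nucleiCount) {
  if (!is.finite(nucleiCount) || nucleiCount < 1) return(NA_real_)
  pbCountRaw / nucleiCount
}

#' Colocalize two channels' particle sets
#'
#' Pixelwise intersection of the two binary particle masks, relabeled
#' into connected components; components smaller than \code{minAreaPx2}
#' are dropped but no circularity filter is applied (intersections of
#' circular foci need not be circular). Areas are those of the
#' intersections, which are smaller than either channel's particle
#' areas when the marker overlap is partial.
#'
#' @param setRed,setGreen \linkS4class{ParticleSet}s from the same field.
#' @param minAreaPx2 minimum intersection area retained.
#' @param intensityImgs optional list of the two background-subtracted
#'   images; when given, mean colocalized intensity is measured on their
#'   average.
#' @param pixelSizeNm pixel size for diameter conversion.
#' @return A \linkS4class{ParticleSet} of colocalized particles.
#' @export
colocalize <- function(setRed, setGreen, minAreaPx2 = 3,
                       intensityImgs = NULL, pixelSizeNm = 102.33) {
  stopifnot(is(setRed, "ParticleSet"), is(setGreen, "ParticleSet"))
  if (!identical(dim(setRed@mask), dim(setGreen@mask)))
    stop("particle masks have mismatched field dimensions")
  inter <- setRed@mask & setGreen@mask
  labels <- labelParticles(inter)
  params <- detectionParams("red", minAreaPx2 = minAreaPx2,
                            maxAreaPx2 = Inf, circMin = 0, circMax = 1)
  ii <- if (is.null(intensityImgs)) matrix(NA_real_, nrow(inter), ncol(inter))
        else (.as_matrix(intensityImgs[[1]]) +
              .as_matrix(intensityImgs[[2]])) / 2
  filterParticles(labels, params, intensityImg = ii,
                  pixelSizeNm = pixelSizeNm,
                  fieldId = paste0(setRed@fieldId, "+", setGreen@fieldId))
}

#' Summarize one field into a metrics row
#'
#' Assembles the per-field quantities used by the time-course analysis:
#' raw and cell-area-normalized particle count, mean particle intensity
#' and area (averaged over the field's retained particles; missing when
#' the field has none), nuclei count, particles per cell, and
#' colocalization summaries when a colocalized set is supplied.
#'
#' @param particleSet \linkS4class{ParticleSet} of the quantified
#'   channel.
#' @param cellAreaFraction cell-covered fraction from [cellMask()].
#' @param nucleiCount nuclei count, or \code{NA} if unavailable.
#' @param colocSet optional colocalized \linkS4class{ParticleSet}.
#' @param timeH,marker,fieldId metadata carried into the row.
#' @return One-row \code{data.frame}.
#' @export
summarizeField <- function(particleSet, cellAreaFraction,
                           nucleiCount = NA_integer_, colocSet = NULL,
                           timeH = NA_real_, marker = "",
                           fieldId = particleSet@fieldId) {
  p <- particles(particleSet)
  n <- nrow(p)
  colocN <- if (is.null(colocSet)) NA_integer_ else length(colocSet)
  data.frame(
    field_id = fieldId, time_h = timeH, marker = marker,
    pb_count_raw = n,
    cell_area_fraction = cellAreaFraction,
    pb_count_norm = normalizeCount(n, cellAreaFraction),
    mean_intensity = if (n) mean(p$mean_intensity) else NA_real_,
    mean_area_px2 = if (n) mean(p$area_px2) else NA_real_,
    mean_diameter_nm = if (n) mean(p$equivalent_diameter_nm) else NA_real_,
    nuclei_count = nucleiCount,
    pb_per_cell = pbPerCell(n, nucleiCount),
    coloc_count_raw = colocN,
    coloc_count_norm = if (is.null(colocSet)) NA_real_ else
      normalizeCount(colocN, cellAreaFraction),
    coloc_mean_area_px2 = if (is.null(colocSet) || !length(colocSet))
      NA_real_ else mean(particles(colocSet)$area_px2))
}
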