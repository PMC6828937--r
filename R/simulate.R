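## Synthetic multi-channel fields with ground truth. The generator
## renders an irregular cell mask, dim nuclei in the DAPI channel and
## diffraction-limited foci as isotropic 2-D Gaussian spots whose count,
## peak brightness and cross-section follow cosine programs, then adds
## shot-like and read noise and quantizes to 8 bits.

#' Evaluate a cosine program
#'
#' \eqn{value(t) = mesor + amplitude \cdot \cos(2\pi (t - phase)/period)}.
#'
#' @param program an \linkS4class{OscillationProgram}.
#' @param tH time in hours (vectorized).
#' @return Program value(s) at \code{tH}.
#' @examples
#' oscillationValue(oscillationProgram(10, 4, 24, 8), 8)  # 14, peak
#' @export
oscillationValue <- function(program, tH) {
  stopifnot(is(program, "OscillationProgram"))
  validObject(program)
  program@mesor + program@amplitude *
    cos(2 * pi * (tH - program@phaseH) / program@periodH)
}

## Deterministic per-field seed derived from (base seed, time, index).
.field_seed <- function(rngSeed, tH, fieldIndex) {
  s <- (as.double(rngSeed) * 2654435.0 + round(tH * 16) * 40503.0 +
        as.double(fieldIndex) * 97.0) %% 2147483629
  as.integer(s)
}

## Evaluate an RNG-consuming expression under a private seed, restoring
## the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Smoothed-noise cell mask occupying (approximately exactly) the target
## fraction of the field: coarse Gaussian noise, blurred, bilinearly
## upsampled, thresholded at the matching quantile.
.cell_mask <- function(nr, nc, fraction) {
  if (fraction >= 1) return(matrix(TRUE, nr, nc))
  cnr <- max(8L, ceiling(nr / 32)); cnc <- max(8L, ceiling(nc / 32))
  coarse <- gaussianBlur(matrix(stats::rnorm(cnr * cnc), cnr, cnc), 1.5)
  ri <- seq(1, cnr, length.out = nr)
  ci <- seq(1, cnc, length.out = nc)
  rlo <- pmin(floor(ri), cnr - 1L); rw <- ri - rlo
  clo <- pmin(floor(ci), cnc - 1L); cw <- ci - clo
  a <- coarse[cbind(rep(rlo, nc), rep(clo, each = nr))]
  b <- coarse[cbind(rep(rlo + 1, nc), rep(clo, each = nr))]
  cc <- coarse[cbind(rep(rlo, nc), rep(clo + 1, each = nr))]
  d <- coarse[cbind(rep(rlo + 1, nc), rep(clo + 1, each = nr))]
  rwv <- rep(rw, nc); cwv <- rep(cw, each = nr)
  up <- matrix((1 - rwv) * (1 - cwv) * a + rwv * (1 - cwv) * b +
               (1 - rwv) * cwv * cc + rwv * cwv * d, nr, nc)
  thr <- stats::quantile(up, 1 - fraction, names = FALSE)
  up >= thr
}

## Add an isotropic Gaussian spot to a matrix, in place by window.
.render_spot <- function(m, row, col, sigma, peak) {
  r <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - r)); r1 <- min(nrow(m), ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(ncol(m), ceiling(col + r))
  if (r0 > r1 || c0 > c1) return(m)
  dr <- (r0:r1) - row; dc <- (c0:c1) - col
  g <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2)) * peak
  m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + g
  m
}

## Soft-edged nucleus blob (logistic edge profile).
.render_nucleus <- function(m, row, col, radius, peak, edge = 3) {
  r <- ceiling(radius + 4 * edge)
  r0 <- max(1L, floor(row - r)); r1 <- min(nrow(m), ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(ncol(m), ceiling(col + r))
  dr <- (r0:r1) - row; dc <- (c0:c1) - col
  d <- sqrt(outer(dr^2, dc^2, "+"))
  m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + peak / (1 + exp((d - radius) / edge))
  m
}

.quantize8 <- function(m) round(pmin(pmax(m, 0), 255))  # m first: keep dims

#' Generate one synthetic field with ground truth
#'
#' Renders one microscope field at fixation time \code{tH}: an irregular
#' cell region, nuclei in the DAPI channel, and spot counts drawn
#' Poisson around the count program with diameters and peak amplitudes
#' from the configured distributions; a \code{colocFraction} share of
#' spots appears at identical centers in both red and green, the rest
#' split between the two channels. Shot noise (Poisson, gain-scaled) and
#' additive read noise are applied and the image is clipped to [0, 255]
#' and quantized. Identical \code{(config, tH, fieldIndex)} reproduce
#' identical pixels; the caller's RNG state is left untouched.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param tH fixation time (hours), on the design grid for time-course
#'   use (not enforced for single fields).
#' @param fieldIndex integer replicate index within the timepoint.
#' @param channels subset of \code{c("red", "green", "dapi")} to render.
#' @return A list with \code{images} (named list of
#'   \linkS4class{FieldImage}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' cfg <- sceneConfig(fieldWPx = 128, fieldHPx = 96,
#'   countProgram = oscillationProgram(6, 2, 24, 8),
#'   nucleiMean = 2, nucleiSd = 0)
#' f <- generateField(cfg, tH = 8, fieldIndex = 1, channels = "red")
#' nrow(f$truth@spots)
#' @export
generateField <- function(config, tH, fieldIndex = 1L,
                          channels = c("red", "green", "dapi")) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  channels <- match.arg(channels, several.ok = TRUE)
  lambda <- oscillationValue(config@countProgram, tH)
  if (lambda < 0) stop("expected per-field count is negative at t=", tH)
  seed <- .field_seed(config@rngSeed, tH, fieldIndex)
  .with_seed(seed, {
    nr <- config@fieldHPx; nc <- config@fieldWPx
    mask <- .cell_mask(nr, nc, config@cellAreaFraction)
    cellFrac <- mean(mask)
    ## spot population
    n <- stats::rpois(1, lambda)
    scale <- sqrt(max(0, oscillationValue(config@areaProgram, tH)) /
                  config@areaProgram@mesor)
    peak0 <- oscillationValue(config@intensityProgram, tH)
    inCell <- which(mask)
    spots <- data.frame(center_row = numeric(0), center_col = numeric(0),
                        diameter_nm = numeric(0), peak = numeric(0),
                        channel = character(0))
    if (n > 0 && length(inCell)) {
      ## n is the expected per-channel count: a colocFraction share is
      ## shared between red and green, the remainder is channel-private
      nBoth <- stats::rbinom(1, n, config@colocFraction)
      memb <- c(rep("both", nBoth), rep("red", n - nBoth),
                rep("green", n - nBoth))
      nTot <- length(memb)
      pos <- sample(inCell, nTot, replace = TRUE)
      rows <- (pos - 1L) %% nr + 1L + stats::runif(nTot, -0.5, 0.5)
      cols <- (pos - 1L) %/% nr + 1L + stats::runif(nTot, -0.5, 0.5)
      dia <- pmax(100, stats::rnorm(nTot, config@pbDiameterMeanNm * scale,
                                    config@pbDiameterSdNm))
      peak <- pmax(5, stats::rnorm(nTot, peak0, 0.12 * abs(peak0)))
      spots <- data.frame(center_row = rows, center_col = cols,
                          diameter_nm = dia, peak = peak, channel = memb)
    }
    ## nuclei
    nNuc <- max(0L, as.integer(round(stats::rnorm(1, config@nucleiMean,
                                                  config@nucleiSd))))
    nucRadius <- 28 * config@pixelSizeNm / 102.33  # ~5.7 um diameter
    nucPos <- matrix(numeric(0), 0, 2)
    if (nNuc > 0 && length(inCell)) {
      tries <- 0L
      while (nrow(nucPos) < nNuc && tries < 40L * nNuc) {
        tries <- tries + 1L
        p <- sample(inCell, 1L)
        pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
        ok <- !nrow(nucPos) ||
          all((nucPos[, 1] - pr)^2 + (nucPos[, 2] - pc)^2 >
              (2.4 * nucRadius)^2)
        if (ok) nucPos <- rbind(nucPos, c(pr, pc))
      }
      nNuc <- nrow(nucPos)
    } else nNuc <- 0L
    ## render channels
    sigmaPx <- spots$diameter_nm / (2.355 * config@pixelSizeNm)
    base <- matrix(config@backgroundFree, nr, nc)
    base[mask] <- config@backgroundCell
    imgs <- list()
    for (ch in channels) {
      m <- base
      if (ch == "dapi") {
        if (nNuc > 0)
          for (i in seq_len(nNuc))
            m <- .render_nucleus(m, nucPos[i, 1], nucPos[i, 2],
                                 nucRadius, 110)
      } else {
        sel <- which(spots$channel %in% c("both", ch))
        for (i in sel)
          m <- .render_spot(m, spots$center_row[i], spots$center_col[i],
                            sigmaPx[i], spots$peak[i])
      }
      if (config@poissonGain > 0)
        m <- stats::rpois(length(m), config@poissonGain * m) /
          config@poissonGain
      if (config@readNoiseSd > 0)
        m <- m + stats::rnorm(length(m), 0, config@readNoiseSd)
      m <- .quantize8(matrix(m, nr, nc))
      marker <- switch(ch, red = "GE-1/HEDLS", green = "DDX6",
                       dapi = "DAPI")
      imgs[[ch]] <- fieldImage(m, channel = ch, marker = marker,
                               timeH = tH,
                               pixelSizeNm = config@pixelSizeNm)
    }
    truth <- new("GroundTruth", spots = spots, nucleiCount = nNuc,
                 cellAreaFraction = cellFrac)
    list(images = imgs, truth = truth)
  })
}

#' Generate a full synthetic time course on disk
#'
#' Writes one 8-bit grayscale TIFF per field per channel for the design
#' grid of the configuration, plus a manifest table (file, timepoint_h,
#' field_index, channel, marker) and a ground-truth table.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param outDir writable output directory (created if needed).
#' @param channels channels to render.
#' @return Invisibly, a list with \code{manifest} and \code{truth}
#'   data.frames (also written as CSV in \code{outDir}).
#' @export
generateTimecourse <- function(config, outDir,
                               channels = c("red", "green", "dapi")) {
  stopifnot(is(config, "SceneConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  tps <- config@tStartH + (seq_len(config@nTimepoints) - 1L) * config@tStepH
  manifest <- NULL
  truthRows <- NULL
  for (tH in tps) {
    for (f in seq_len(config@fieldsPerTimepoint)) {
      fld <- generateField(config, tH, f, channels = channels)
      for (ch in names(fld$images)) {
        img <- fld$images[[ch]]
        file <- sprintf("t%03d_f%02d_%s.tif", as.integer(round(tH)), f, ch)
        path <- file.path(outDir, file)
        ok <- try(tiff::writeTIFF(pixels(img) / 255, path,
                                  bits.per.sample = 8L), silent = TRUE)
        if (inherits(ok, "try-error"))
          stop("failed to write ", path, ": ", attr(ok, "condition")$message)
        manifest <- rbind(manifest, data.frame(
          file = file, timepoint_h = tH, field_index = f, channel = ch,
          marker = markerName(img)))
      }
      tr <- fld$truth
      truthRows <- rbind(truthRows, data.frame(
        timepoint_h = tH, field_index = f,
        true_spots = nrow(tr@spots),
        true_spots_red = sum(tr@spots$channel %in% c("red", "both")),
        true_spots_green = sum(tr@spots$channel %in% c("green", "both")),
        true_spots_both = sum(tr@spots$channel == "both"),
        nuclei = tr@nucleiCount, cell_area_fraction = tr@cellAreaFraction,
        mean_diameter_nm = if (nrow(tr@spots))
          mean(tr@spots$diameter_nm) else NA_real_))
    }
  }
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truthRows, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, truth = truthRows))
}

#' Read a field TIFF back as a FieldImage
#'
#' @param path TIFF file written by [generateTimecourse()] (8-bit
#'   grayscale).
#' @param channel,marker,timeH,pixelSizeNm metadata to attach.
#' @return A \linkS4class{FieldImage} with pixels in [0, 255].
#' @export
readFieldTiff <- function(path, channel = "red", marker = "",
                          timeH = NA_real_, pixelSizeNm = 102.33) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  fieldImage(round(m * 255), channel = channel, marker = marker,
             timeH = timeH, pixelSizeNm = pixelSizeNm)
}
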