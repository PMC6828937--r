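## Detection chain: blur -> rolling-ball background subtraction ->
## threshold -> 8-connectivity labeling -> size/circularity filter.
## All processing is floating point; quantization happens only on file
## output.

.as_matrix <- function(img) {
  if (is(img, "FieldImage")) img@pixels else img
}

.wrap_like <- function(img, m) {
  if (is(img, "FieldImage")) {
    out <- img
    out@pixels <- m
    out
  } else m
}

#' Isotropic Gaussian blur with reflective borders
#'
#' Separable convolution with a truncated Gaussian kernel (radius
#' \code{ceiling(4 sigma)}), borders handled by mirror reflection.
#' \code{sigmaPx = 0} is the identity.
#'
#' @param img a \linkS4class{FieldImage} or numeric matrix.
#' @param sigmaPx Gaussian sigma in pixels, non-negative.
#' @return Blurred image of the same class as the input.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1
#' sum(gaussianBlur(m, 0.8))  # mass conserved
#' @export
gaussianBlur <- function(img, sigmaPx = 0.8) {
  if (!is.numeric(sigmaPx) || length(sigmaPx) != 1L || sigmaPx < 0)
    stop("sigmaPx must be a non-negative scalar")
  m <- .as_matrix(img)
  if (sigmaPx == 0) return(.wrap_like(img, m))
  r <- max(1L, as.integer(ceiling(4 * sigmaPx)))
  k <- exp(-(-r:r)^2 / (2 * sigmaPx^2))
  k <- k / sum(k)
  m <- .conv1d(m, k, r, dim = 1L)
  m <- .conv1d(m, k, r, dim = 2L)
  .wrap_like(img, m)
}

## 1-D convolution along rows (dim=1) or columns (dim=2) with mirror
## reflection at the borders, vectorized as shifted-matrix accumulation.
.conv1d <- function(m, k, r, dim) {
  n <- if (dim == 1L) nrow(m) else ncol(m)
  idx <- seq_len(n)
  out <- matrix(0, nrow(m), ncol(m))
  for (o in -r:r) {
    j <- idx + o
    # reflect without repeating the edge pixel (style "abc|cba")
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    # second pass for very small images
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    w <- k[o + r + 1L]
    out <- out + w * (if (dim == 1L) m[j, , drop = FALSE]
                      else m[, j, drop = FALSE])
  }
  out
}

## Offsets and heights of the ball (spherical cap) structuring element.
.ball_se <- function(radiusPx) {
  r <- ceiling(radiusPx)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radiusPx^2
  g <- g[keep, ]
  list(dr = as.integer(g$dr), dc = as.integer(g$dc),
       h = sqrt(pmax(0, radiusPx^2 - g$dr^2 - g$dc^2)))
}

#' Rolling-ball background estimate
#'
#' The slowly varying background of an image is estimated as its
#' grayscale morphological opening by a ball (spherical cap) structuring
#' element: the upper envelope of a ball of the given radius rolled
#' beneath the intensity surface. Structures narrower than the ball
#' (punctate foci) are excluded from the background.
#'
#' @param img a \linkS4class{FieldImage} or numeric matrix.
#' @param radiusPx ball radius in pixels, positive.
#' @return Background image, same class as input.
#' @seealso [subtractBackground()]
#' @export
rollingBallBackground <- function(img, radiusPx = 5) {
  if (!is.numeric(radiusPx) || length(radiusPx) != 1L || radiusPx <= 0)
    stop("radiusPx must be a positive scalar")
  m <- .as_matrix(img)
  se <- .ball_se(radiusPx)
  er <- .cpp_grey_erode(m, se$dr, se$dc, se$h)
  bg <- .cpp_grey_dilate(er, se$dr, se$dc, se$h)
  .wrap_like(img, bg)
}

#' Subtract the rolling-ball background
#'
#' Returns \code{img - rollingBallBackground(img, radiusPx)} floored at
#' zero. The result is everywhere non-negative and no larger than the
#' input (an opening never exceeds the image).
#'
#' @inheritParams rollingBallBackground
#' @return Background-subtracted image, same class as input.
#' @export
subtractBackground <- function(img, radiusPx = 5) {
  m <- .as_matrix(img)
  bg <- .as_matrix(rollingBallBackground(m, radiusPx))
  .wrap_like(img, pmax(m - bg, 0))
}

#' Fixed-intensity threshold
#'
#' Selects pixels with intensity greater than or equal to \code{lower}
#' (inclusive lower bound; the upper bound is the 8-bit maximum). The
#' operation is stateless so the same constant can be applied to every
#' image of an experiment.
#'
#' @param img a \linkS4class{FieldImage} or numeric matrix.
#' @param lower inclusive lower bound in [0, 255].
#' @return Logical matrix mask.
#' @export
applyThreshold <- function(img, lower) {
  if (!is.numeric(lower) || length(lower) != 1L || lower < 0 || lower > 255)
    stop("lower must be a scalar in [0, 255]")
  .as_matrix(img) >= lower
}

#' Label connected particles
#'
#' Connected components of a binary mask under 8-connectivity (diagonal
#' neighbours are connected), labels 1..K, background 0.
#'
#' @param mask logical matrix.
#' @return Integer label matrix.
#' @export
labelParticles <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix")
  .cpp_label8(mask)
}

#' Shape circularity of labeled regions
#'
#' Circularity \eqn{4\pi \cdot area / perimeter^2}, capped at 1; a value
#' of 1 corresponds to a perfect circle. Perimeters are measured by
#' tracing the outer contour and summing boundary steps (diagonal steps
#' weighted \eqn{\sqrt 2}); single-pixel regions are assigned
#' circularity 1 by convention.
#'
#' @param labels integer label matrix (from [labelParticles()]).
#' @return Numeric vector of circularities, one per label 1..K.
#' @export
particleCircularity <- function(labels) {
  nlab <- max(labels)
  if (nlab == 0L) return(numeric(0))
  areas <- tabulate(labels[labels > 0L], nbins = nlab)
  if (any(areas == 0L)) stop("labels must be consecutive 1..K")
  per <- .cpp_region_perimeters(labels, nlab)
  circ <- ifelse(per > 0, pmin(1, 4 * pi * areas / per^2), 1)
  circ
}

#' Equivalent physical diameter of a particle
#'
#' Diameter of the circle with the particle's pixel area, converted to
#' nanometers: \eqn{d = p \cdot 2\sqrt{A/\pi}} for pixel size \eqn{p}
#' (nm/px) and area \eqn{A} (px^2). With the default calibration of
#' 102.33 nm/px, the 3 and 300 px^2 area cut-offs of the particle filter
#' correspond to 200 and 2000 nm.
#'
#' @param areaPx2 particle area in px^2, positive.
#' @param pixelSizeNm pixel size in nm/px, positive.
#' @return Equivalent diameter in nm.
#' @examples
#' equivalentDiameterNm(3, 102.33)    # ~200 nm
#' equivalentDiameterNm(300, 102.33)  # ~2000 nm
#' @export
equivalentDiameterNm <- function(areaPx2, pixelSizeNm = 102.33) {
  if (any(areaPx2 <= 0) || pixelSizeNm <= 0)
    stop("areaPx2 and pixelSizeNm must be positive")
  pixelSizeNm * 2 * sqrt(areaPx2 / pi)
}

#' Filter labeled regions into a particle set
#'
#' Retains regions whose area lies in \code{[minAreaPx2, maxAreaPx2]}
#' and whose circularity lies in \code{[circMin, circMax]}, and measures
#' each retained particle: area, contour perimeter, circularity,
#' centroid, mean intensity over the region on the supplied
#' background-subtracted image (optionally also on the raw image) and
#' equivalent physical diameter.
#'
#' @param labels integer label matrix.
#' @param params a \linkS4class{DetectionParams}.
#' @param intensityImg background-subtracted image (matrix or
#'   \linkS4class{FieldImage}) on which mean intensities are measured.
#' @param rawImg optional raw image for diagnostic intensities.
#' @param pixelSizeNm pixel size used for diameter conversion; defaults
#'   to the \code{intensityImg} metadata when available.
#' @param fieldId identifier stored in the result.
#' @return A \linkS4class{ParticleSet}.
#' @export
filterParticles <- function(labels, params, intensityImg, rawImg = NULL,
                            pixelSizeNm = NULL, fieldId = "") {
  stopifnot(is(params, "DetectionParams"))
  if (is.null(pixelSizeNm))
    pixelSizeNm <- if (is(intensityImg, "FieldImage"))
      intensityImg@pixelSizeNm else 102.33
  ii <- .as_matrix(intensityImg)
  ri <- if (is.null(rawImg)) NULL else .as_matrix(rawImg)
  nlab <- max(labels)
  empty <- data.frame(label = integer(0), area_px2 = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_intensity = numeric(0),
                      raw_mean_intensity = numeric(0),
                      equivalent_diameter_nm = numeric(0))
  if (nlab == 0L)
    return(new("ParticleSet", particles = empty,
               mask = matrix(FALSE, nrow(labels), ncol(labels)),
               fieldId = fieldId))
  pos <- which(labels > 0L)
  lab <- labels[pos]
  areas <- tabulate(lab, nbins = nlab)
  per <- .cpp_region_perimeters(labels, nlab)
  circ <- ifelse(per > 0, pmin(1, 4 * pi * areas / per^2), 1)
  rows <- (pos - 1L) %% nrow(labels) + 1L
  cols <- (pos - 1L) %/% nrow(labels) + 1L
  cr <- rowsum(as.numeric(rows), lab)[, 1] / areas
  cc <- rowsum(as.numeric(cols), lab)[, 1] / areas
  mi <- rowsum(ii[pos], lab)[, 1] / areas
  rmi <- if (is.null(ri)) rep(NA_real_, nlab) else
    rowsum(ri[pos], lab)[, 1] / areas
  keep <- which(areas >= params@minAreaPx2 & areas <= params@maxAreaPx2 &
                circ >= params@circMin & circ <= params@circMax)
  p <- data.frame(label = keep, area_px2 = as.numeric(areas[keep]),
                  perimeter_px = per[keep], circularity = circ[keep],
                  centroid_row = cr[keep], centroid_col = cc[keep],
                  mean_intensity = mi[keep], raw_mean_intensity = rmi[keep],
                  equivalent_diameter_nm = if (length(keep))
                    equivalentDiameterNm(areas[keep], pixelSizeNm)
                  else numeric(0))
  mask <- matrix(FALSE, nrow(labels), ncol(labels))
  if (length(keep)) mask[pos[lab %in% keep]] <- TRUE
  new("ParticleSet", particles = p, mask = mask, fieldId = fieldId)
}

#' Detect punctate foci in one channel of one field
#'
#' The full detection chain: Gaussian blur, rolling-ball background
#' subtraction, fixed inclusive threshold, 8-connectivity labeling and
#' size/circularity filtering. Mean particle intensities are measured on
#' the blurred background-subtracted floating-point image (and on the
#' raw image for diagnostics). Deterministic for fixed input and
#' parameters.
#'
#' @param img a \linkS4class{FieldImage} (or numeric matrix) holding the
#'   8-bit channel.
#' @param params a \linkS4class{DetectionParams}; defaults to the red
#'   channel settings.
#' @param fieldId identifier stored in the result.
#' @return A \linkS4class{ParticleSet}.
#' @examples
#' m <- matrix(5, 64, 64)
#' m[20:24, 20:24] <- 120
#' length(detectFoci(m, detectionParams("red")))
#' @export
detectFoci <- function(img, params = detectionParams("red"),
                       fieldId = "") {
  blurred <- gaussianBlur(img, params@blurSigmaPx)
  sub <- subtractBackground(blurred, params@rollingBallRadiusPx)
  mask <- applyThreshold(sub, params@threshold)
  labels <- labelParticles(mask)
  filterParticles(labels, params, intensityImg = sub, rawImg = img,
                  pixelSizeNm = if (is(img, "FieldImage"))
                    img@pixelSizeNm else NULL,
                  fieldId = fieldId)
}
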