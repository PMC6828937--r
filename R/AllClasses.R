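#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib PunctaCycle, .registration = TRUE
NULL

#' Cosine oscillation program
#'
#' Parameterizes the expected value of a metric over circadian time as
#' \eqn{m + A \cos(2\pi (t - \phi)/T)}: \code{mesor} is the rhythm-adjusted
#' mean level (metric units), \code{amplitude} the half peak-to-trough
#' excursion (same units), \code{periodH} the period and \code{phaseH} the
#' acrophase (time of peak), both in hours.
#'
#' @slot mesor numeric(1) baseline level.
#' @slot amplitude numeric(1), non-negative.
#' @slot periodH numeric(1), hours, strictly positive.
#' @slot phaseH numeric(1), hours; peak time modulo the period.
#' @exportClass OscillationProgram
setClass("OscillationProgram",
  representation(mesor = "numeric", amplitude = "numeric",
                 periodH = "numeric", phaseH = "numeric"),
  prototype(mesor = 0, amplitude = 0, periodH = 24, phaseH = 0))

setValidity("OscillationProgram", function(object) {
  msg <- NULL
  for (s in c("mesor", "amplitude", "periodH", "phaseH")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (is.null(msg)) {
    if (object@periodH <= 0) msg <- c(msg, "periodH must be > 0")
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param mesor,amplitude,periodH,phaseH see slot descriptions.
#' @return An \code{OscillationProgram}.
#' @examples
#' oscillationProgram(10, 4, 24, 8)
#' @rdname OscillationProgram-class
#' @export
oscillationProgram <- function(mesor, amplitude = 0, periodH = 24,
                               phaseH = 0) {
  new("OscillationProgram", mesor = as.numeric(mesor),
      amplitude = as.numeric(amplitude), periodH = as.numeric(periodH),
      phaseH = as.numeric(phaseH))
}

#' Synthetic scene configuration
#'
#' Describes the study conditions emulated by the synthetic-field
#' generator: field geometry and bit depth, the design grid of fixation
#' times, per-field nuclei statistics, the focal-spot diameter
#' distribution, the cosine programs driving count, per-spot brightness
#' and spot cross-section over time, the colocalized fraction of spots,
#' and the noise model.
#'
#' The defaults emulate a dexamethasone-synchronized neuroblastoma
#' time course: 1376 x 1038 px 8-bit fields at 102.33 nm/px, 16
#' timepoints from 8 h to 68 h every 4 h, 20 fields per timepoint,
#' 23.6 +/- 9.1 nuclei per field and spots of 476 +/- 60 nm diameter.
#'
#' @slot fieldWPx,fieldHPx integer field size in pixels.
#' @slot bitDepth integer, fixed at 8.
#' @slot pixelSizeNm numeric, physical pixel size (nm/px).
#' @slot nTimepoints,tStartH,tStepH design grid (count, start h, step h).
#' @slot fieldsPerTimepoint integer fields imaged per timepoint.
#' @slot nucleiMean,nucleiSd per-field nuclei count distribution.
#' @slot pbDiameterMeanNm,pbDiameterSdNm focal-spot diameter distribution.
#' @slot countProgram,intensityProgram,areaProgram cosine programs for
#'   expected per-field spot count, per-spot peak brightness (8-bit counts
#'   above background) and relative spot cross-section (px^2; spot
#'   diameters are scaled by \code{sqrt(value/mesor)} so the mesor maps to
#'   \code{pbDiameterMeanNm}).
#' @slot colocFraction fraction of spots present in both red and green.
#' @slot cellAreaFraction target fraction of the field covered by cells.
#' @slot backgroundCell,backgroundFree background level inside/outside the
#'   cell mask (8-bit counts).
#' @slot poissonGain photons per count for shot noise (0 disables noise).
#' @slot readNoiseSd additive Gaussian read noise sd (counts).
#' @slot rngSeed integer base seed; field seeds derive from it.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(fieldWPx = "integer", fieldHPx = "integer",
    bitDepth = "integer", pixelSizeNm = "numeric",
    nTimepoints = "integer", tStartH = "numeric", tStepH = "numeric",
    fieldsPerTimepoint = "integer",
    nucleiMean = "numeric", nucleiSd = "numeric",
    pbDiameterMeanNm = "numeric", pbDiameterSdNm = "numeric",
    countProgram = "OscillationProgram",
    intensityProgram = "OscillationProgram",
    areaProgram = "OscillationProgram",
    colocFraction = "numeric", cellAreaFraction = "numeric",
    backgroundCell = "numeric", backgroundFree = "numeric",
    poissonGain = "numeric", readNoiseSd = "numeric",
    rngSeed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- NULL
  if (object@fieldWPx < 8L || object@fieldHPx < 8L)
    msg <- c(msg, "field dimensions must be >= 8 px")
  if (object@bitDepth != 8L)
    msg <- c(msg, "only 8-bit output is supported")
  if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be > 0")
  if (object@nTimepoints < 1L || object@tStepH <= 0)
    msg <- c(msg, "design grid must have >= 1 timepoint and step > 0")
  if (object@fieldsPerTimepoint < 1L)
    msg <- c(msg, "fieldsPerTimepoint must be >= 1")
  if (object@colocFraction < 0 || object@colocFraction > 1)
    msg <- c(msg, "colocFraction must be in [0, 1]")
  if (object@cellAreaFraction <= 0 || object@cellAreaFraction > 1)
    msg <- c(msg, "cellAreaFraction must be in (0, 1]")
  cp <- object@countProgram
  if (cp@amplitude > cp@mesor)
    msg <- c(msg, "count program amplitude must not exceed its mesor")
  if (is.null(msg)) TRUE else msg
})

#' @param fieldWPx,fieldHPx,pixelSizeNm,nTimepoints,tStartH,tStepH,fieldsPerTimepoint,nucleiMean,nucleiSd,pbDiameterMeanNm,pbDiameterSdNm,countProgram,intensityProgram,areaProgram,colocFraction,cellAreaFraction,backgroundCell,backgroundFree,poissonGain,readNoiseSd,rngSeed
#'   see slot documentation.
#' @return A \code{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(fieldWPx = 256, fieldHPx = 192, fieldsPerTimepoint = 2)
#' @rdname SceneConfig-class
#' @export
sceneConfig <- function(fieldWPx = 1376L, fieldHPx = 1038L,
    pixelSizeNm = 102.33, nTimepoints = 16L, tStartH = 8, tStepH = 4,
    fieldsPerTimepoint = 20L, nucleiMean = 23.6, nucleiSd = 9.1,
    pbDiameterMeanNm = 476, pbDiameterSdNm = 60,
    countProgram = oscillationProgram(240, 55, 24, 6.5),
    intensityProgram = oscillationProgram(85, 5, 24, 6.5),
    areaProgram = oscillationProgram(17, 1, 24, 6.5),
    colocFraction = 0.6, cellAreaFraction = 0.85,
    backgroundCell = 12, backgroundFree = 2,
    poissonGain = 1, readNoiseSd = 2, rngSeed = 1L) {
  new("SceneConfig", fieldWPx = as.integer(fieldWPx),
      fieldHPx = as.integer(fieldHPx), bitDepth = 8L,
      pixelSizeNm = pixelSizeNm, nTimepoints = as.integer(nTimepoints),
      tStartH = tStartH, tStepH = tStepH,
      fieldsPerTimepoint = as.integer(fieldsPerTimepoint),
      nucleiMean = nucleiMean, nucleiSd = nucleiSd,
      pbDiameterMeanNm = pbDiameterMeanNm,
      pbDiameterSdNm = pbDiameterSdNm, countProgram = countProgram,
      intensityProgram = intensityProgram, areaProgram = areaProgram,
      colocFraction = colocFraction, cellAreaFraction = cellAreaFraction,
      backgroundCell = backgroundCell, backgroundFree = backgroundFree,
      poissonGain = poissonGain, readNoiseSd = readNoiseSd,
      rngSeed = as.integer(rngSeed))
}

#' One channel of one micrograph field
#'
#' A single-channel image with acquisition metadata. Pixels are stored as
#' a numeric matrix (rows = image rows); 8-bit input images hold values
#' in [0, 255], while intermediate processed images (blurred,
#' background-subtracted) are floating point and may leave that range.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot channel character, one of "red", "green", "dapi".
#' @slot marker character, biological marker imaged in this channel.
#' @slot timeH numeric, hours post-synchronization.
#' @slot pixelSizeNm numeric, nm per pixel.
#' @exportClass FieldImage
setClass("FieldImage",
  representation(pixels = "matrix", channel = "character",
                 marker = "character", timeH = "numeric",
                 pixelSizeNm = "numeric"),
  prototype(channel = "red", marker = "", timeH = NA_real_,
            pixelSizeNm = 102.33))

setValidity("FieldImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
    msg <- c(msg, "image must be non-empty")
  if (!object@channel %in% c("red", "green", "dapi"))
    msg <- c(msg, "channel must be red, green or dapi")
  if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param pixels,channel,marker,timeH,pixelSizeNm see slot documentation.
#' @return A \code{FieldImage}.
#' @rdname FieldImage-class
#' @export
fieldImage <- function(pixels, channel = "red", marker = "",
                       timeH = NA_real_, pixelSizeNm = 102.33) {
  new("FieldImage", pixels = pixels, channel = channel, marker = marker,
      timeH = timeH, pixelSizeNm = pixelSizeNm)
}

#' Particle detection parameters
#'
#' Parameters of the four-step detection chain: Gaussian blur sigma,
#' rolling-ball radius, fixed intensity threshold and the size and
#' circularity filters applied to connected components. The threshold is
#' a per-experiment constant (40 for the red channel, 35 for green by
#' default) and is never adapted per image, so that all timepoints are
#' compared on an equal footing.
#'
#' @slot blurSigmaPx numeric Gaussian blur sigma (px).
#' @slot rollingBallRadiusPx numeric rolling-ball radius (px).
#' @slot threshold numeric lower intensity bound, inclusive, in [0, 255].
#' @slot minAreaPx2,maxAreaPx2 numeric retained area range (px^2).
#' @slot circMin,circMax numeric retained circularity range.
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(blurSigmaPx = "numeric", rollingBallRadiusPx = "numeric",
                 threshold = "numeric", minAreaPx2 = "numeric",
                 maxAreaPx2 = "numeric", circMin = "numeric",
                 circMax = "numeric"))

setValidity("DetectionParams", function(object) {
  msg <- NULL
  if (object@blurSigmaPx < 0) msg <- c(msg, "blurSigmaPx must be >= 0")
  if (object@rollingBallRadiusPx <= 0)
    msg <- c(msg, "rollingBallRadiusPx must be > 0")
  if (object@threshold < 0 || object@threshold > 255)
    msg <- c(msg, "threshold must be in [0, 255]")
  if (!(object@minAreaPx2 > 0 && object@minAreaPx2 < object@maxAreaPx2))
    msg <- c(msg, "need 0 < minAreaPx2 < maxAreaPx2")
  if (!(object@circMin >= 0 && object@circMin <= object@circMax &&
        object@circMax <= 1))
    msg <- c(msg, "need 0 <= circMin <= circMax <= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param channel picks the default threshold: 40 (red), 35 (green).
#' @param blurSigmaPx,rollingBallRadiusPx,threshold,minAreaPx2,maxAreaPx2,circMin,circMax
#'   see slot documentation; an explicit \code{threshold} overrides the
#'   channel default.
#' @return A \code{DetectionParams}.
#' @examples
#' detectionParams("green")
#' @rdname DetectionParams-class
#' @export
detectionParams <- function(channel = c("red", "green"),
    blurSigmaPx = 0.8, rollingBallRadiusPx = 5,
    threshold = NULL, minAreaPx2 = 3, maxAreaPx2 = 300,
    circMin = 0.7, circMax = 1) {
  channel <- match.arg(channel)
  if (is.null(threshold)) threshold <- if (channel == "red") 40 else 35
  new("DetectionParams", blurSigmaPx = blurSigmaPx,
      rollingBallRadiusPx = rollingBallRadiusPx, threshold = threshold,
      minAreaPx2 = minAreaPx2, maxAreaPx2 = maxAreaPx2,
      circMin = circMin, circMax = circMax)
}

#' Set of detected particles
#'
#' Holds the per-particle table produced by the detection chain (label,
#' area, perimeter, circularity, centroid, mean intensity on the
#' background-subtracted image, raw-image mean intensity and equivalent
#' physical diameter) together with the binary mask of retained pixels.
#'
#' @slot particles data.frame, one row per retained particle.
#' @slot mask logical matrix; union of the particle pixel sets.
#' @slot fieldId character identifier of the source field/channel.
#' @exportClass ParticleSet
setClass("ParticleSet",
  representation(particles = "data.frame", mask = "matrix",
                 fieldId = "character"),
  prototype(fieldId = ""))

setValidity("ParticleSet", function(object) {
  need <- c("label", "area_px2", "perimeter_px", "circularity",
            "centroid_row", "centroid_col", "mean_intensity",
            "equivalent_diameter_nm")
  miss <- setdiff(need, names(object@particles))
  if (length(miss))
    return(paste("particles lacks columns:", paste(miss, collapse = ", ")))
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' Per-timepoint groups of a per-field metric
#'
#' The statistical unit of the time-course analysis: for one metric, the
#' per-field replicate values grouped by fixation time. Group means are
#' the series handed to the rhythm-detection methods; the per-field
#' values feed the Kruskal-Wallis/Dunn comparisons.
#'
#' @slot metric character metric name.
#' @slot data data.frame with columns time_h, field_id, value.
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(metric = "character", data = "data.frame"))

setValidity("TimeCourse", function(object) {
  d <- object@data
  if (!all(c("time_h", "field_id", "value") %in% names(d)))
    return("data needs columns time_h, field_id, value")
  if (nrow(d) < 1L) return("empty time course")
  if (any(!is.finite(d$time_h))) return("non-finite timepoints")
  TRUE
})

#' @param metric metric name.
#' @param timeH,value,fieldId parallel vectors of per-field observations.
#' @return A \code{TimeCourse}.
#' @rdname TimeCourse-class
#' @export
timeCourse <- function(metric, timeH, value, fieldId = seq_along(value)) {
  keep <- is.finite(value)
  new("TimeCourse", metric = metric,
      data = data.frame(time_h = timeH[keep],
                        field_id = as.character(fieldId)[keep],
                        value = value[keep]))
}

#' Result of rhythm detection with method integration
#'
#' Per-method (Lomb-Scargle "LS", rank-concordance "JTK", autoregressive
#' harmonic "ARS") p-value, period, phase and amplitude, plus the
#' integrated consensus record.
#'
#' @slot methods data.frame with columns method, p, period_h, phase_h,
#'   amplitude.
#' @slot integrated list with elements p, period_h, phase_h, amplitude.
#' @exportClass RhythmResult
setClass("RhythmResult",
  representation(methods = "data.frame", integrated = "list"))

#' Kruskal-Wallis plus Dunn post hoc result
#'
#' @slot H numeric tie-corrected Kruskal-Wallis statistic.
#' @slot p numeric chi-square p-value.
#' @slot pairwise data.frame of pairwise Dunn comparisons (group_i,
#'   group_j, z, p_adjusted).
#' @exportClass KWDunnResult
setClass("KWDunnResult",
  representation(H = "numeric", p = "numeric", pairwise = "data.frame"))

#' Fitted cosine curve
#'
#' Least-squares cosinor fit \eqn{y = M + A\cos(2\pi(t-\phi)/T)} at a
#' fixed period.
#'
#' @slot mesor,amplitude,phaseH,periodH fitted parameters; \code{phaseH}
#'   (acrophase) lies in [0, period) and is NA when the amplitude is
#'   indistinguishable from zero.
#' @slot rss residual sum of squares.
#' @exportClass CosineFit
setClass("CosineFit",
  representation(mesor = "numeric", amplitude = "numeric",
                 phaseH = "numeric", periodH = "numeric", rss = "numeric"))

#' Ground truth of a synthetic field
#'
#' @slot spots data.frame of rendered spots (center_row, center_col,
#'   diameter_nm, peak, channel membership "red"/"green"/"both").
#' @slot nucleiCount integer number of rendered nuclei.
#' @slot cellAreaFraction numeric true fraction of pixels inside cells.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(spots = "data.frame", nucleiCount = "integer",
                 cellAreaFraction = "numeric"))
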