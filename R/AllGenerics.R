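#' Accessors for image and particle containers
#'
#' \code{pixels} returns the intensity matrix of a \linkS4class{FieldImage};
#' \code{channelName}, \code{markerName}, \code{timeH} and
#' \code{pixelSizeNm} return its metadata. \code{particles} returns the
#' per-particle table of a \linkS4class{ParticleSet} and
#' \code{particleMask} its binary mask.
#'
#' @param object a \code{FieldImage} or \code{ParticleSet}.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("markerName", function(object) standardGeneric("markerName"))
#' @rdname accessors
#' @export
setGeneric("timeH", function(object) standardGeneric("timeH"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeNm", function(object) standardGeneric("pixelSizeNm"))
#' @rdname accessors
#' @export
setGeneric("particles", function(object) standardGeneric("particles"))
#' @rdname accessors
#' @export
setGeneric("particleMask", function(object) standardGeneric("particleMask"))

#' @rdname accessors
#' @export
setMethod("pixels", "FieldImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("channelName", "FieldImage", function(object) object@channel)
#' @rdname accessors
#' @export
setMethod("markerName", "FieldImage", function(object) object@marker)
#' @rdname accessors
#' @export
setMethod("timeH", "FieldImage", function(object) object@timeH)
#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "FieldImage", function(object) object@pixelSizeNm)
#' @rdname accessors
#' @export
setMethod("particles", "ParticleSet", function(object) object@particles)
#' @rdname accessors
#' @export
setMethod("particleMask", "ParticleSet", function(object) object@mask)

#' @param x a \code{ParticleSet}.
#' @describeIn accessors number of retained particles.
#' @export
setMethod("length", "ParticleSet", function(x) nrow(x@particles))

setMethod("show", "FieldImage", function(object) {
  cat(sprintf("FieldImage %dx%d px, channel=%s marker=%s t=%sh, %.2f nm/px\n",
              nrow(object@pixels), ncol(object@pixels), object@channel,
              if (nzchar(object@marker)) object@marker else "<unset>",
              format(object@timeH), object@pixelSizeNm))
})

setMethod("show", "ParticleSet", function(object) {
  p <- object@particles
  cat(sprintf("ParticleSet '%s': %d particles\n", object@fieldId, nrow(p)))
  if (nrow(p))
    cat(sprintf("  area %.1f-%.1f px^2, mean diameter %.0f nm\n",
                min(p$area_px2), max(p$area_px2),
                mean(p$equivalent_diameter_nm)))
})

setMethod("show", "TimeCourse", function(object) {
  d <- object@data
  tp <- sort(unique(d$time_h))
  cat(sprintf("TimeCourse '%s': %d observations, %d timepoints (%g-%g h)\n",
              object@metric, nrow(d), length(tp), min(tp), max(tp)))
})

setMethod("show", "RhythmResult", function(object) {
  cat("RhythmResult\n")
  print(object@methods, row.names = FALSE, digits = 4)
  i <- object@integrated
  cat(sprintf("integrated: p=%.3g period=%.2fh phase=%.2fh amplitude=%.3g\n",
              i$p, i$period_h, i$phase_h, i$amplitude))
})

setMethod("show", "CosineFit", function(object) {
  cat(sprintf(
    "CosineFit: mesor=%.4g amplitude=%.4g phase=%.4gh period=%.4gh rss=%.4g\n",
    object@mesor, object@amplitude, object@phaseH, object@periodH,
    object@rss))
})

setMethod("show", "KWDunnResult", function(object) {
  cat(sprintf("Kruskal-Wallis H=%.4g, p=%.3g; %d pairwise comparisons\n",
              object@H, object@p, nrow(object@pairwise)))
})

#' @param object a \code{TimeCourse}.
#' @describeIn timeCourse per-timepoint mean/SEM/n summary table.
#' @export
setGeneric("timepointSummary",
           function(object) standardGeneric("timepointSummary"))

#' @rdname timeCourse
#' @export
setMethod("timepointSummary", "TimeCourse", function(object) {
  d <- object@data
  sp <- split(d$value, d$time_h)
  data.frame(time_h = as.numeric(names(sp)),
             mean = vapply(sp, mean, 0),
             sem = vapply(sp, function(v)
               if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               0),
             n = vapply(sp, length, 0L), row.names = NULL)
})
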