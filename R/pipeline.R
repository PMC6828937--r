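## Orchestration: manifest-driven detection, end-to-end runs, YAML
## configs, config hashing and Figure-style plots.

#' Run configuration for manifest-driven processing
#'
#' Per-channel detection parameters (fixed thresholds per experiment),
#' pixel size, rhythm settings and seed.
#'
#' @slot paramsRed,paramsGreen \linkS4class{DetectionParams}.
#' @slot pixelSizeNm numeric.
#' @slot periodRange numeric(2), hours.
#' @slot rhythmMode "means" or "fields".
#' @slot seed integer.
#' @slot logLevel "quiet", "info" or "debug".
#' @exportClass RunConfig
setClass("RunConfig",
  representation(paramsRed = "DetectionParams",
                 paramsGreen = "DetectionParams",
                 pixelSizeNm = "numeric", periodRange = "numeric",
                 rhythmMode = "character", seed = "integer",
                 logLevel = "character"))

#' @param paramsRed,paramsGreen,pixelSizeNm,periodRange,rhythmMode,seed,logLevel
#'   see slot documentation.
#' @return A \code{RunConfig}.
#' @rdname RunConfig-class
#' @export
runConfig <- function(paramsRed = detectionParams("red"),
                      paramsGreen = detectionParams("green"),
                      pixelSizeNm = 102.33, periodRange = c(20, 28),
                      rhythmMode = "means", seed = 1L,
                      logLevel = "info") {
  new("RunConfig", paramsRed = paramsRed, paramsGreen = paramsGreen,
      pixelSizeNm = pixelSizeNm, periodRange = periodRange,
      rhythmMode = rhythmMode, seed = as.integer(seed),
      logLevel = logLevel)
}

.log <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config@logLevel]] >= lv[[level]])
    message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Stable hash of a run configuration
#'
#' MD5 of the configuration's deparsed slots; recorded in output
#' artifacts so that results can be traced to the exact settings that
#' produced them.
#'
#' @param config a \linkS4class{RunConfig} or \linkS4class{SceneConfig}.
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
  txt <- paste(deparse(lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (isVirtualClass(class(v)) || is(v, "DetectionParams") ||
        is(v, "OscillationProgram"))
      lapply(slotNames(v), function(s2) slot(v, s2))
    else v
  })), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Read / write a scene configuration as YAML
#'
#' @param path YAML file mirroring the \linkS4class{SceneConfig} fields
#'   (programs as nested maps with mesor/amplitude/period_h/phase_h).
#' @return \code{readSceneConfig} returns a \linkS4class{SceneConfig};
#'   \code{writeSceneConfig} writes one and returns the path invisibly.
#' @export
readSceneConfig <- function(path) {
  y <- yaml::read_yaml(path)
  prog <- function(p, default) {
    if (is.null(p)) return(default)
    oscillationProgram(p$mesor, p$amplitude, p$period_h, p$phase_h)
  }
  d <- formals(sceneConfig)
  arg <- function(nm, default) if (is.null(y[[nm]])) default else y[[nm]]
  sceneConfig(
    fieldWPx = arg("field_w_px", eval(d$fieldWPx)),
    fieldHPx = arg("field_h_px", eval(d$fieldHPx)),
    pixelSizeNm = arg("pixel_size_nm", eval(d$pixelSizeNm)),
    nTimepoints = arg("n_timepoints", eval(d$nTimepoints)),
    tStartH = arg("t_start_h", eval(d$tStartH)),
    tStepH = arg("t_step_h", eval(d$tStepH)),
    fieldsPerTimepoint = arg("fields_per_timepoint",
                             eval(d$fieldsPerTimepoint)),
    nucleiMean = arg("nuclei_mean", eval(d$nucleiMean)),
    nucleiSd = arg("nuclei_sd", eval(d$nucleiSd)),
    pbDiameterMeanNm = arg("pb_diameter_mean_nm", eval(d$pbDiameterMeanNm)),
    pbDiameterSdNm = arg("pb_diameter_sd_nm", eval(d$pbDiameterSdNm)),
    countProgram = prog(y$count_program, eval(d$countProgram)),
    intensityProgram = prog(y$intensity_program, eval(d$intensityProgram)),
    areaProgram = prog(y$area_program, eval(d$areaProgram)),
    colocFraction = arg("coloc_fraction", eval(d$colocFraction)),
    cellAreaFraction = arg("cell_area_fraction", eval(d$cellAreaFraction)),
    backgroundCell = arg("background_cell", eval(d$backgroundCell)),
    backgroundFree = arg("background_free", eval(d$backgroundFree)),
    poissonGain = arg("poisson_gain", eval(d$poissonGain)),
    readNoiseSd = arg("read_noise_sd", eval(d$readNoiseSd)),
    rngSeed = arg("rng_seed", eval(d$rngSeed)))
}

#' @param config a \linkS4class{SceneConfig} to serialize.
#' @rdname readSceneConfig
#' @export
writeSceneConfig <- function(config, path) {
  pr <- function(p) list(mesor = p@mesor, amplitude = p@amplitude,
                         period_h = p@periodH, phase_h = p@phaseH)
  yaml::write_yaml(list(
    field_w_px = config@fieldWPx, field_h_px = config@fieldHPx,
    pixel_size_nm = config@pixelSizeNm,
    n_timepoints = config@nTimepoints, t_start_h = config@tStartH,
    t_step_h = config@tStepH,
    fields_per_timepoint = config@fieldsPerTimepoint,
    nuclei_mean = config@nucleiMean, nuclei_sd = config@nucleiSd,
    pb_diameter_mean_nm = config@pbDiameterMeanNm,
    pb_diameter_sd_nm = config@pbDiameterSdNm,
    count_program = pr(config@countProgram),
    intensity_program = pr(config@intensityProgram),
    area_program = pr(config@areaProgram),
    coloc_fraction = config@colocFraction,
    cell_area_fraction = config@cellAreaFraction,
    background_cell = config@backgroundCell,
    background_free = config@backgroundFree,
    poisson_gain = config@poissonGain,
    read_noise_sd = config@readNoiseSd,
    rng_seed = config@rngSeed), path)
  invisible(path)
}

#' Detect particles for every field of a manifest
#'
#' Processes a manifest (as written by [generateTimecourse()]: columns
#' file, timepoint_h, field_index, channel, marker) grouped by field:
#' reads the TIFFs, runs the detection chain on each cytoplasmic
#' channel with that channel's fixed parameters, builds the cell mask,
#' counts nuclei when a DAPI channel is present, colocalizes red and
#' green when both are present, and returns one metrics row per field
#' per cytoplasmic channel (plus colocalization columns). Unreadable
#' files skip the affected field with a warning; rows are sorted so
#' reruns are byte-identical.
#'
#' @param manifest data.frame or path to the manifest CSV.
#' @param config a \linkS4class{RunConfig}.
#' @param dir directory containing the image files (defaults to the
#'   manifest's directory when a path is given).
#' @return data.frame of per-field metrics; attribute
#'   \code{config_hash} carries [configHash()].
#' @export
runDetect <- function(manifest, config = runConfig(), dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  need <- c("file", "timepoint_h", "field_index", "channel")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  if (is.null(manifest$marker)) manifest$marker <- manifest$channel
  chans <- unique(manifest$channel[manifest$channel != "dapi"])
  for (ch in chans)
    if (!ch %in% c("red", "green"))
      stop("no detection parameters for channel: ", ch)
  keys <- unique(manifest[, c("timepoint_h", "field_index")])
  keys <- keys[order(keys$timepoint_h, keys$field_index), ]
  rows <- list()
  nfail <- 0L
  for (i in seq_len(nrow(keys))) {
    tH <- keys$timepoint_h[i]; f <- keys$field_index[i]
    sub <- manifest[manifest$timepoint_h == tH &
                    manifest$field_index == f, ]
    imgs <- list()
    bad <- FALSE
    for (j in seq_len(nrow(sub))) {
      path <- file.path(dir, sub$file[j])
      im <- try(readFieldTiff(path, channel = sub$channel[j],
                              marker = sub$marker[j], timeH = tH,
                              pixelSizeNm = config@pixelSizeNm),
                silent = TRUE)
      if (inherits(im, "try-error")) {
        warning("skipping field t=", tH, " f=", f,
                ": unreadable file ", path)
        bad <- TRUE
        break
      }
      imgs[[sub$channel[j]]] <- im
    }
    if (bad) { nfail <- nfail + 1L; next }
    cyto <- imgs[setdiff(names(imgs), "dapi")]
    cm <- cellMask(cyto)
    nuc <- if ("dapi" %in% names(imgs)) countNuclei(imgs$dapi)
           else NA_integer_
    sets <- list()
    subImgs <- list()
    for (ch in names(cyto)) {
      pars <- if (ch == "red") config@paramsRed else config@paramsGreen
      blur <- gaussianBlur(cyto[[ch]], pars@blurSigmaPx)
      subI <- subtractBackground(blur, pars@rollingBallRadiusPx)
      lab <- labelParticles(applyThreshold(subI, pars@threshold))
      sets[[ch]] <- filterParticles(lab, pars, intensityImg = subI,
                                    rawImg = cyto[[ch]],
                                    pixelSizeNm = config@pixelSizeNm,
                                    fieldId = sprintf("t%g_f%d_%s",
                                                      tH, f, ch))
      subImgs[[ch]] <- subI
    }
    coloc <- if (all(c("red", "green") %in% names(sets)))
      colocalize(sets$red, sets$green,
                 minAreaPx2 = config@paramsRed@minAreaPx2,
                 intensityImgs = subImgs[c("red", "green")],
                 pixelSizeNm = config@pixelSizeNm) else NULL
    for (ch in names(sets)) {
      rows[[length(rows) + 1L]] <- summarizeField(
        sets[[ch]], cm$fraction, nucleiCount = nuc, colocSet = coloc,
        timeH = tH, marker = sub$marker[match(ch, sub$channel)],
        fieldId = sprintf("t%g_f%d_%s", tH, f, ch))
      .log(config, "debug", "t=", tH, " f=", f, " ", ch, ": ",
           length(sets[[ch]]), " particles")
    }
  }
  if (!length(rows))
    stop("all manifest rows failed; no field could be processed")
  out <- do.call(rbind, rows)
  out <- out[order(out$time_h, out$field_id), ]
  rownames(out) <- NULL
  attr(out, "config_hash") <- configHash(config)
  attr(out, "n_failed_fields") <- nfail
  out
}

#' Build per-metric time courses from a metrics table
#'
#' @param metrics data.frame from [runDetect()].
#' @param metric column to extract (e.g. \code{"pb_count_norm"}).
#' @param marker optional marker filter.
#' @return A \linkS4class{TimeCourse}.
#' @export
timeCourseFromMetrics <- function(metrics, metric = "pb_count_norm",
                                  marker = NULL) {
  d <- metrics
  if (!is.null(marker)) d <- d[d$marker == marker, ]
  if (!nrow(d)) stop("no rows for marker ", marker)
  timeCourse(paste0(metric, if (!is.null(marker)) paste0("_", marker)),
             d$time_h, d[[metric]], d$field_id)
}

#' End-to-end pipeline run
#'
#' Simulate (optional) -> detect -> per-timepoint grouping ->
#' statistical analysis of normalized count, mean intensity and mean
#' area per marker plus the colocalized count, with results tables,
#' a JSON summary and cosine-fitted time-course plots.
#'
#' @param scene a \linkS4class{SceneConfig} to simulate, or \code{NULL}
#'   to use an existing dataset.
#' @param config a \linkS4class{RunConfig}.
#' @param outDir output directory; also receives the simulated images
#'   when \code{scene} is given and \code{imageDir} is NULL.
#' @param imageDir directory with an existing manifest.csv + TIFFs.
#' @param channels channels to simulate/process.
#' @param plots write per-metric PNG plots.
#' @return List with \code{metrics} (per-field rows), \code{results}
#'   (tidy statistics table) and \code{analyses} (per-metric
#'   [analyzeTimecourse()] outputs), invisibly; files are written to
#'   \code{outDir}.
#' @export
runFull <- function(scene = sceneConfig(), config = runConfig(),
                    outDir = tempfile("punctacycle"), imageDir = NULL,
                    channels = c("red", "green", "dapi"),
                    plots = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(imageDir)) {
    if (is.null(scene)) stop("either a scene config or imageDir is needed")
    imageDir <- file.path(outDir, "images")
    .log(config, "info", "simulating time course [stage: simulate]")
    generateTimecourse(scene, imageDir, channels = channels)
  }
  .log(config, "info", "detecting particles [stage: detect]")
  metrics <- runDetect(file.path(imageDir, "manifest.csv"), config)
  utils::write.csv(metrics, file.path(outDir, "field_metrics.csv"),
                   row.names = FALSE)
  .log(config, "info", "rhythm analysis [stage: analyze]")
  analyses <- list()
  results <- NULL
  markers <- unique(metrics$marker)
  for (mk in markers) {
    for (met in c("pb_count_norm", "mean_intensity", "mean_area_px2")) {
      tc <- timeCourseFromMetrics(metrics, met, marker = mk)
      nm <- paste0(met, "_", mk)
      a <- try(analyzeTimecourse(tc, periodRange = config@periodRange,
                                 mode = config@rhythmMode), silent = TRUE)
      if (inherits(a, "try-error")) {
        warning("analysis failed for ", nm, " [stage: analyze]")
        next
      }
      analyses[[nm]] <- a
      results <- rbind(results, a$table)
      if (plots) .plot_fit(tc, a$fit, file.path(outDir,
                                                paste0(nm, ".png")))
    }
  }
  if (!is.na(match("coloc_count_norm", names(metrics))) &&
      any(is.finite(metrics$coloc_count_norm))) {
    sub <- metrics[metrics$marker == markers[1] &
                   is.finite(metrics$coloc_count_norm), ]
    if (nrow(sub)) {
      tc <- timeCourse("coloc_count_norm", sub$time_h,
                       sub$coloc_count_norm, sub$field_id)
      a <- try(analyzeTimecourse(tc, periodRange = config@periodRange,
                                 mode = config@rhythmMode), silent = TRUE)
      if (!inherits(a, "try-error")) {
        analyses$coloc_count_norm <- a
        results <- rbind(results, a$table)
      }
    }
  }
  hash <- configHash(config)
  resFile <- file.path(outDir, "results.csv")
  if (file.exists(resFile)) {
    prev <- readLines(resFile, n = 1L)
    if (grepl("^# config ", prev) &&
        !identical(prev, paste("# config", hash)))
      stop("refusing to overwrite ", resFile,
           ": existing results carry a different config hash")
  }
  con <- file(resFile, "w")
  writeLines(paste("# config", hash), con)
  utils::write.csv(results, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(config_hash = hash,
         integrated = lapply(analyses, function(a) a$rhythm@integrated)),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, results = results,
                 analyses = analyses, config_hash = hash))
}

#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_line
#'   labs theme_bw ggsave
.plot_fit <- function(tc, fit, path) {
  s <- timepointSummary(tc)
  tt <- seq(min(s$time_h), max(s$time_h), length.out = 200)
  ph <- if (is.finite(fit@phaseH)) fit@phaseH else 0
  curve <- data.frame(
    time_h = tt,
    value = fit@mesor + fit@amplitude *
      cos(2 * pi * (tt - ph) / fit@periodH))
  g <- ggplot(s, aes(x = time_h, y = mean)) +
    geom_errorbar(aes(ymin = mean - sem, ymax = mean + sem), width = 1) +
    geom_point() +
    geom_line(data = curve, aes(y = value), colour = "red") +
    labs(x = "time post-synchronization (h)", y = tc@metric) +
    theme_bw()
  ggsave(path, g, width = 6, height = 4, dpi = 120)
  invisible(path)
}

#' Published per-timepoint mean PB-number series
#'
#' Per-timepoint means of the normalized processing-body count
#' (count per field scaled to full cell coverage) for the two markers
#' GE-1/HEDLS and DDX6 in dexamethasone-synchronized Neuro 2A cells,
#' 16 timepoints from 8 to 68 h post-synchronization every 4 h,
#' shipped as plain CSV in \code{inst/extdata}. These printed summary
#' series are the worked-example input for the rhythm layer.
#'
#' @return data.frame with columns time_h, marker, mean.
#' @examples
#' head(pbNumberSeries())
#' @export
pbNumberSeries <- function() {
  utils::read.csv(system.file("extdata", "pb_number_means.csv",
                              package = "PunctaCycle"))
}
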