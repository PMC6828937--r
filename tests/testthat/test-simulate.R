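test_that("cosine programs evaluate and validate", {
  expect_equal(oscillationValue(oscillationProgram(10, 4, 24, 8), 8), 14)
  expect_equal(oscillationValue(oscillationProgram(10, 0, 24, 0),
                                c(1, 7, 13)), rep(10, 3))
  grid <- 0:23
  expect_equal(mean(oscillationValue(oscillationProgram(10, 4, 24, 0),
                                     grid)), 10, tolerance = 1e-12)
  expect_error(oscillationProgram(10, 4, periodH = 0), "periodH")
  expect_error(oscillationProgram(10, -1), "amplitude")
  expect_error(sceneConfig(countProgram = oscillationProgram(5, 9)),
               "amplitude")
})

test_that("field generation is bitwise deterministic and RNG-clean", {
  cfg <- small_config()
  set.seed(999); before <- runif(1)
  f1 <- generateField(cfg, 12, 3)
  f2 <- generateField(cfg, 12, 3)
  for (ch in names(f1$images))
    expect_identical(pixels(f1$images[[ch]]), pixels(f2$images[[ch]]))
  expect_identical(f1$truth@spots, f2$truth@spots)
  # different field index gives different pixels
  f3 <- generateField(cfg, 12, 4)
  expect_false(identical(pixels(f1$images$red), pixels(f3$images$red)))
  # caller RNG stream unaffected
  set.seed(999); expect_identical(runif(1), before)
})

test_that("noiseless well-separated spots are conserved through detection", {
  f <- generateField(five_spot_config(), 8, 1, channels = "red")
  expect_identical(nrow(f$truth@spots), 5L)
  ps <- detectFoci(f$images$red, detectionParams("red"))
  expect_identical(length(ps), 5L)
  # noiseless equality holds across several draws, whatever N is
  for (s in c(21L, 22L)) {
    cfg <- five_spot_config(); cfg@rngSeed <- s
    f <- generateField(cfg, 8, 1, channels = "red")
    ps <- detectFoci(f$images$red, detectionParams("red"))
    expect_identical(length(ps), nrow(f$truth@spots))
  }
})

test_that("generated time course writes a coherent manifest", {
  cfg <- small_config(fieldWPx = 96, fieldHPx = 72, nTimepoints = 2L,
                      fieldsPerTimepoint = 1L,
                      countProgram = oscillationProgram(4, 0, 24, 0),
                      nucleiMean = 1, nucleiSd = 0)
  out <- file.path(tempdir(), "tc-test")
  res <- generateTimecourse(cfg, out)
  expect_identical(nrow(res$manifest), 2L * 1L * 3L)
  expect_true(all(file.exists(file.path(out, res$manifest$file))))
  tp <- unique(res$manifest$timepoint_h)
  expect_identical(tp, c(8, 12))
  expect_true(all(diff(tp) == 4))
  # grid arithmetic of the default design
  d <- sceneConfig()
  tps <- d@tStartH + (seq_len(d@nTimepoints) - 1) * d@tStepH
  expect_identical(range(tps), c(8, 68))
  expect_identical(length(tps), 16L)
  # TIFF roundtrip preserves pixels
  img <- readFieldTiff(file.path(out, res$manifest$file[1]))
  orig <- generateField(cfg, 8, 1)$images[[res$manifest$channel[1]]]
  expect_identical(pixels(img), pixels(orig))
  unlink(out, recursive = TRUE)
})

test_that("per-timepoint true counts recover the cosine program", {
  cfg <- small_config(fieldWPx = 96, fieldHPx = 72,
                      fieldsPerTimepoint = 20L,
                      countProgram = oscillationProgram(30, 12, 24, 8))
  tps <- cfg@tStartH + (seq_len(cfg@nTimepoints) - 1) * cfg@tStepH
  means <- vapply(tps, function(tt) {
    mean(vapply(seq_len(20), function(f) {
      sp <- generateField(cfg, tt, f, channels = "red")$truth@spots
      sum(sp$channel %in% c("red", "both"))  # per-channel program
    }, 0))
  }, 0)
  fit <- cosinorFit(tps, means, 24)
  seMesor <- sqrt(mean(means) / (20 * length(tps)))
  expect_lt(abs(fit@mesor - 30), 3 * seMesor * sqrt(1))
  seAmp <- seMesor * sqrt(2)
  expect_lt(abs(fit@amplitude - 12), 3 * seAmp)
  expect_lt(abs(fit@phaseH - 8), 1)
})

test_that("spot membership respects the colocalized fraction", {
  cfg <- small_config(countProgram = oscillationProgram(200, 0, 24, 0),
                      colocFraction = 0.6)
  sp <- generateField(cfg, 8, 1, channels = "red")$truth@spots
  nRed <- sum(sp$channel %in% c("both", "red"))
  nGreen <- sum(sp$channel %in% c("both", "green"))
  expect_identical(nRed, nGreen)  # per-channel counts follow one program
  frac <- sum(sp$channel == "both") / nRed
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nRed))
  expect_true(all(sp$channel %in% c("both", "red", "green")))
})
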