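test_that("cell mask recovers the covered fraction", {
  f <- generateField(small_config(), 8, 1)
  cm <- cellMask(f$images[c("red", "green")])
  expect_lt(abs(cm$fraction - f$truth@cellAreaFraction), 0.07)
  full <- generateField(small_config(cellAreaFraction = 1), 8, 1,
                        channels = "red")
  expect_gte(cellMask(full$images$red)$fraction, 0.98)
  expect_warning(cm0 <- cellMask(matrix(0, 64, 64)), "blank")
  expect_lt(cm0$fraction, 0.01)
  expect_error(cellMask(fieldImage(matrix(0, 8, 8), channel = "dapi")),
               "cytoplasmic")
})

test_that("count normalization scales by covered fraction", {
  expect_equal(normalizeCount(100, 1), 100)
  expect_equal(normalizeCount(100, 0.5), 200)
  expect_equal(normalizeCount(0, 0.3), 0)
  expect_equal(normalizeCount(2 * 50, 0.8), 2 * normalizeCount(50, 0.8))
  expect_error(normalizeCount(10, 0), "> 0")
})

test_that("nuclei counting is exact for disjoint nuclei and 0 for blank", {
  dapi <- matrix(3, 600, 800)
  ctr <- expand.grid(row = seq(60, 540, by = 120),
                     col = seq(60, 740, by = 170))  # 5 x 5 disjoint
  for (i in seq_len(20))
    dapi <- draw_disk(dapi, ctr$row[i], ctr$col[i], 28, 120)
  expect_identical(countNuclei(dapi), 20L)
  expect_identical(countNuclei(matrix(2, 100, 100)), 0L)
})

test_that("nuclei recovery on the default field size stays within 15%", {
  cfg <- sceneConfig(countProgram = oscillationProgram(40, 0, 24, 0))
  counts <- vapply(1:5, function(i) {
    f <- generateField(cfg, 8, i, channels = "dapi")
    c(countNuclei(f$images$dapi), f$truth@nucleiCount)
  }, c(0, 0))
  expect_lt(abs(mean(counts[1, ]) / mean(counts[2, ]) - 1), 0.15)
})

test_that("particles per cell handles zero nuclei as missing", {
  expect_equal(pbPerCell(10, 5), 2)
  expect_equal(pbPerCell(0, 4), 0)
  expect_true(is.na(pbPerCell(10, 0)))
})

test_that("colocalization intersects particle masks", {
  m <- matrix(0, 60, 60)
  m <- draw_disk(m, 20, 20, 2.9, 1)
  m <- draw_disk(m, 40, 40, 2.9, 1)
  labels <- labelParticles(m > 0)
  pars <- detectionParams("red")
  psA <- filterParticles(labels, pars, m * 100)
  # identical masks: same count and areas
  cc <- colocalize(psA, psA)
  expect_identical(length(cc), length(psA))
  expect_equal(sort(particles(cc)$area_px2),
               sort(particles(psA)$area_px2))
  # disjoint masks: nothing
  m2 <- draw_disk(matrix(0, 60, 60), 20, 45, 2.9, 1)
  psB <- filterParticles(labelParticles(m2 > 0), pars, m2 * 100)
  expect_identical(length(colocalize(psA, psB)), 0L)
  expect_error(colocalize(psA, filterParticles(
    labelParticles(matrix(FALSE, 10, 10)), pars, matrix(0, 10, 10))),
    "dimensions")
})

test_that("partial overlap reports the intersection area", {
  # two 28-px^2 disks whose centers differ: intersection ~10 px^2
  a <- draw_disk(matrix(0, 40, 40), 20, 18, 2.9, 1)
  b <- draw_disk(matrix(0, 40, 40), 20, 22, 2.9, 1)
  inter <- sum(a > 0 & b > 0)
  pars <- detectionParams("red")
  psA <- filterParticles(labelParticles(a > 0), pars, a)
  psB <- filterParticles(labelParticles(b > 0), pars, b)
  cc <- colocalize(psA, psB)
  expect_identical(length(cc), 1L)
  expect_equal(particles(cc)$area_px2, inter)
  expect_lt(particles(cc)$area_px2, particles(psA)$area_px2)
})

test_that("colocalized share tracks the configured fraction", {
  rho <- 0.6
  ratios <- vapply(1:4, function(i) {
    f <- generateField(small_config(colocFraction = rho,
      countProgram = oscillationProgram(60, 0, 24, 0)), 8, i,
      channels = c("red", "green"))
    pr <- detectFoci(f$images$red, detectionParams("red"))
    pg <- detectFoci(f$images$green, detectionParams("green"))
    cc <- colocalize(pr, pg)
    length(cc) / min(length(pr), length(pg))
  }, 0)
  expect_lt(abs(mean(ratios) - rho), 0.1)
})

test_that("field summary assembles Table-style rows", {
  f <- generateField(small_config(), 8, 2)
  ps <- detectFoci(f$images$red, detectionParams("red"))
  cm <- cellMask(f$images[c("red", "green")])
  row <- summarizeField(ps, cm$fraction, nucleiCount = 3L, timeH = 8,
                        marker = "GE-1/HEDLS")
  expect_identical(row$pb_count_raw, length(ps))
  expect_gte(row$pb_count_norm, row$pb_count_raw)
  expect_true(row$mean_area_px2 >= 3 && row$mean_area_px2 <= 300)
  expect_equal(row$mean_area_px2, mean(particles(ps)$area_px2))
  expect_equal(row$pb_per_cell, length(ps) / 3)
  # empty set: count 0, means missing
  blank <- detectFoci(matrix(5, 64, 64), detectionParams("red"))
  row0 <- summarizeField(blank, 0.9)
  expect_identical(row0$pb_count_raw, 0L)
  expect_true(is.na(row0$mean_intensity) && is.na(row0$mean_area_px2))
})

test_that("colocalized count never exceeds either channel", {
  for (i in 1:3) {
    f <- generateField(small_config(seed = 30L + i), 8 + 4 * i, 1,
                       channels = c("red", "green"))
    pr <- detectFoci(f$images$red, detectionParams("red"))
    pg <- detectFoci(f$images$green, detectionParams("green"))
    cc <- colocalize(pr, pg)
    expect_lte(length(cc), min(length(pr), length(pg)))
  }
})
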