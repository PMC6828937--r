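test_that("gaussian blur is the identity at sigma 0 and conserves mass", {
  set.seed(11)
  m <- matrix(runif(30 * 40, 0, 255), 30, 40)
  expect_identical(gaussianBlur(m, 0), m)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  expect_lt(abs(sum(gaussianBlur(imp, 0.8)) - 1), 1e-6)
  expect_error(gaussianBlur(m, -1), "non-negative")
})

test_that("gaussian blur matches the dense convolution oracle", {
  set.seed(12)
  for (sigma in c(0.8, 1.5)) {
    m <- matrix(runif(9 * 9, 0, 255), 9, 9)
    expect_lt(max(abs(gaussianBlur(m, sigma) - oracle_blur(m, sigma))),
              1e-9)
  }
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_lt(max(abs(gaussianBlur(imp, 0.8) - oracle_blur(imp, 0.8))),
            1e-12)
})

test_that("rolling-ball background removes flat fields and bounds output", {
  flat <- matrix(50, 20, 20)
  expect_true(all(subtractBackground(flat, 5) == 0))
  set.seed(13)
  m <- matrix(runif(30 * 30, 0, 255), 30, 30)
  sub <- subtractBackground(m, 5)
  expect_true(all(sub >= 0))
  expect_true(all(sub <= m + 1e-12))
  expect_error(subtractBackground(m, 0), "positive")
})

test_that("rolling-ball equals brute-force ball opening on small images", {
  set.seed(14)
  m <- matrix(runif(24 * 24, 0, 120), 24, 24)
  bg <- rollingBallBackground(m, 5)
  expect_lt(max(abs(bg - oracle_opening(m, 5))), 1e-9)
  bg3 <- rollingBallBackground(m, 3)
  expect_lt(max(abs(bg3 - oracle_opening(m, 3))), 1e-9)
})

test_that("a narrow spike on a ramp survives background subtraction", {
  nr <- 48; nc <- 64
  ramp <- matrix(rep(seq(0, 31.5, length.out = nc), each = nr), nr, nc)
  img <- ramp
  img[24:25, 32:33] <- img[24:25, 32:33] + 100  # 2-px-wide spike
  sub <- subtractBackground(img, 5)
  expect_gt(max(sub[24:25, 32:33]), 90)  # spike height kept within 10%
  interior <- sub[11:38, 11:25]          # ramp-only region, away from edges
  expect_lt(max(interior), 5)
})

test_that("threshold is inclusive at the lower bound", {
  m <- matrix(c(39, 40, 41, 0), 2, 2)
  expect_identical(sum(applyThreshold(m, 40)), 2L)
  expect_identical(sum(applyThreshold(matrix(0, 4, 4), 40)), 0L)
  expect_true(all(applyThreshold(m, 0)))
  expect_error(applyThreshold(m, 300), "\\[0, 255\\]")
})

test_that("raising the threshold never grows the mask", {
  set.seed(15)
  m <- matrix(runif(40 * 40, 0, 255), 40, 40)
  counts <- vapply(seq(0, 250, by = 25),
                   function(th) sum(applyThreshold(m, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("labeling uses 8-connectivity and matches flood fill", {
  expect_identical(max(labelParticles(matrix(FALSE, 5, 5))), 0L)
  diag2 <- matrix(FALSE, 4, 4); diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_identical(max(labelParticles(diag2)), 1L)
  checker <- matrix(FALSE, 3, 3)
  checker[cbind(c(1, 1, 2, 3, 3), c(1, 3, 2, 1, 3))] <- TRUE
  expect_identical(max(labelParticles(checker)), 1L)
  set.seed(16)
  for (i in 1:8) {
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    lab <- labelParticles(mask)
    ref <- oracle_flood8(mask)
    expect_identical(max(lab), max(ref))
    # identical partition up to label naming
    expect_true(all(tapply(ref[mask], lab[mask],
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("circularity separates disks from lines, single pixel is 1", {
  m <- matrix(FALSE, 30, 30)
  m <- draw_disk(matrix(0, 30, 30), 15, 15, 10, 1) > 0
  circ <- particleCircularity(labelParticles(m))
  expect_gte(circ, 0.85)
  line <- matrix(FALSE, 10, 30); line[5, 5:24] <- TRUE
  expect_lt(particleCircularity(labelParticles(line)), 0.7)
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_identical(particleCircularity(labelParticles(px)), 1)
})

test_that("particle filter enforces the size window and measures diameter", {
  m <- matrix(0, 80, 120)
  m <- draw_disk(m, 15, 15, 0.9, 1)     # ~2 px^2: rejected
  m <- draw_disk(m, 40, 40, 2.9, 1)     # ~28 px^2: retained
  m <- draw_disk(m, 40, 95, 11.2, 1)    # ~400 px^2: rejected
  labels <- labelParticles(m > 0)
  areas <- tabulate(labels[labels > 0])
  expect_identical(length(areas), 3L)
  expect_lt(areas[1], 3); expect_gt(areas[3], 300)
  ps <- filterParticles(labels, detectionParams("red"),
                        intensityImg = m * 100, pixelSizeNm = 102.33)
  expect_identical(length(ps), 1L)
  p <- particles(ps)
  expect_equal(p$area_px2, areas[2])
  expect_equal(p$equivalent_diameter_nm,
               102.33 * 2 * sqrt(areas[2] / pi), tolerance = 1e-10)
  # 28 px^2 corresponds to ~611 nm
  expect_equal(2 * sqrt(28 / pi) * 102.33, 611, tolerance = 0.01)
})

test_that("equivalent diameter follows the square-root law", {
  expect_equal(equivalentDiameterNm(3, 102.33), 200, tolerance = 1e-2)
  expect_equal(equivalentDiameterNm(300, 102.33), 2000, tolerance = 3e-3)
  a <- runif(5, 1, 100)
  expect_equal(equivalentDiameterNm(4 * a), 2 * equivalentDiameterNm(a))
  expect_error(equivalentDiameterNm(-1), "positive")
})

test_that("full detection chain finds disjoint disks and is deterministic", {
  m <- matrix(10, 200, 200)
  ctr <- cbind(c(30, 70, 110, 150, 170), c(30, 80, 120, 40, 170))
  for (i in 1:5) m <- draw_disk(m, ctr[i, 1], ctr[i, 2], 3, 120)
  ps <- detectFoci(m, detectionParams("red"))
  expect_identical(length(ps), 5L)
  expect_true(all(particles(ps)$circularity >= 0.7))
  expect_identical(length(detectFoci(matrix(7, 100, 100),
                                     detectionParams("red"))), 0L)
  ps2 <- detectFoci(m, detectionParams("red"))
  expect_identical(particles(ps), particles(ps2))
  expect_identical(particleMask(ps), particleMask(ps2))
  # mask equals the union of retained pixels and particles are disjoint
  expect_identical(sum(particleMask(ps)), as.integer(
    sum(particles(ps)$area_px2)))
})
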