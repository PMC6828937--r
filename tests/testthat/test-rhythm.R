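grid16 <- seq(8, 68, by = 4)

test_that("Kruskal-Wallis matches the hand-rank oracle and handles ties", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskalWallis(g)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$H, oracle_kw_H(g), tolerance = 1e-10)
  expect_equal(kruskalWallis(list(c(5, 5, 5), c(5, 5, 5)))$H, 0)
  expect_equal(kruskalWallis(list(c(5, 5, 5), c(5, 5, 5)))$p, 1)
  # rank invariance under a strictly monotone transform
  g2 <- lapply(g, exp)
  expect_equal(kruskalWallis(g2)$H, kw$H)
  set.seed(41)
  g3 <- list(sample(c(1, 2, 3)), sample(c(4, 5, 6)))
  expect_equal(kruskalWallis(g3)$H, kw$H)
})

test_that("Dunn's test matches the mean-rank formula and is antisymmetric", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  d <- dunnTest(g)
  # hand computation: mean ranks 1.5/3.5/5.5, V = 3.5, se = sqrt(3.5)
  expect_equal(d$z, c(-2 / sqrt(3.5), -4 / sqrt(3.5), -2 / sqrt(3.5)),
               tolerance = 1e-10)
  expect_identical(nrow(d), 3L)
  # reversing the group order flips the signs
  d2 <- dunnTest(rev(g))
  expect_equal(d2$z[d2$group_i == "b" & d2$group_j == "a"],
               -d$z[d$group_i == "a" & d$group_j == "b"])
  ident <- dunnTest(list(c(2, 2), c(2, 2)))
  expect_equal(ident$p_adjusted, 1)
  expect_error(dunnTest(list(1:3, numeric(0))), "empty")
})

test_that("Lomb-Scargle recovers a known period and is shift invariant", {
  y <- cos(2 * pi * grid16 / 24)
  ls <- lombScargle(grid16, y)
  expect_lt(abs(ls$period_h - 24), 0.2)  # grid step + spectral leakage
  expect_lt(ls$p, 1e-4)
  const <- lombScargle(grid16, rep(3, 16), calibration = FALSE)
  expect_equal(const$p, 1)
  expect_true(is.na(const$period_h))
  shifted <- lombScargle(grid16, y + 100)
  expect_equal(shifted$p, ls$p)
  expect_equal(shifted$period_h, ls$period_h)
})

test_that("rank-concordance scan finds period and phase of a cosine", {
  y <- cos(2 * pi * (grid16 - 8) / 24)
  jt <- jtkCycle(grid16, y)
  expect_equal(jt$period_h, 24)
  expect_equal(jt$phase_h %% 24, 8)
  expect_lt(jt$p, 0.01)
  # sign flip moves the phase by half a period
  jt2 <- jtkCycle(grid16, -y)
  expect_equal(jt2$phase_h %% 24, (8 + 12) %% 24)
  # permuting a rhythmic series degrades concordance
  set.seed(42)
  perm <- jtkCycle(grid16, sample(y), calibration = FALSE)
  expect_gt(perm$p, jtkCycle(grid16, y, calibration = FALSE)$p)
  ties <- jtkCycle(grid16, rep(1, 16), calibration = FALSE)
  expect_equal(ties$p, 1)
})

test_that("autoregressive harmonic detection is near-exact without noise", {
  y <- 5 + 3 * cos(2 * pi * (grid16 - 8) / 24)
  ar <- arser(grid16, y)
  expect_lt(abs(ar$period_h - 24), 0.5)
  expect_lt(abs(ar$amplitude - 3) / 3, 0.05)
  expect_lt(abs(ar$phase_h - 8), 1)
  expect_lt(ar$p, 1e-6)
  # a pure linear trend carries no rhythm after detrending
  tr <- arser(grid16, 2 + 0.5 * grid16)
  expect_gte(tr$p, 0.05)
  expect_error(arser(c(1, 2, 4, 8, 16, 24, 30, 33), rnorm(8)), "regular")
})

test_that("all three methods ignore constant offsets", {
  set.seed(43)
  y <- cos(2 * pi * grid16 / 24) + rnorm(16, 0, 0.3)
  for (fn in list(lombScargle, jtkCycle, arser)) {
    a <- fn(grid16, y, calibration = FALSE)
    b <- fn(grid16, y + 57, calibration = FALSE)
    expect_equal(b$p, a$p, tolerance = 1e-8)
    expect_equal(b$period_h, a$period_h)
  }
})

test_that("cosinor fit is exact on noiseless data and flags zero amplitude", {
  y <- 10 + 4 * cos(2 * pi * (grid16 - 8) / 24)
  f <- cosinorFit(grid16, y, 24)
  expect_equal(f@mesor, 10, tolerance = 1e-10)
  expect_equal(f@amplitude, 4, tolerance = 1e-10)
  expect_equal(f@phaseH, 8, tolerance = 1e-8)
  flat <- cosinorFit(grid16, rep(2, 16), 24)
  expect_lt(flat@amplitude, 1e-8)
  expect_true(is.na(flat@phaseH))
  expect_error(cosinorFit(rep(1, 5), 1:5, 24), "distinct")
})

test_that("cosinor amplitude bias under white noise stays below sigma", {
  set.seed(44)
  amps <- replicate(1000, {
    y <- 10 + 4 * cos(2 * pi * (grid16 - 8) / 24) + rnorm(16, 0, 1)
    cosinorFit(grid16, y, 24)@amplitude
  })
  expect_lt(abs(mean(amps) - 4), 1)
})

test_that("integration combines p-values, periods and phases sensibly", {
  rec <- function(p, per = 24, ph = 8, a = 1)
    list(p = p, period_h = per, phase_h = ph, amplitude = a)
  r3 <- metaIntegrate(list(LS = rec(.5), JTK = rec(.5), ARS = rec(.5)))
  expect_equal(r3@integrated$p, stats::pchisq(4.159, 6, lower.tail = FALSE),
               tolerance = 1e-3)
  expect_equal(r3@integrated$p, 0.655, tolerance = 1e-3)
  expect_equal(r3@integrated$period_h, 24)
  expect_equal(r3@integrated$phase_h, 8, tolerance = 1e-10)
  single <- metaIntegrate(list(ARS = rec(0.02, 23.5, 6, 2.2)))
  expect_equal(single@integrated,
               list(p = 0.02, period_h = 23.5, phase_h = 6,
                    amplitude = 2.2))
  # circular mean respects wrap-around
  wrap <- metaIntegrate(list(LS = rec(.5, 24, 23.5), JTK = rec(.5, 24, 0.5)))
  expect_lt(min(wrap@integrated$phase_h, 24 - wrap@integrated$phase_h), 1)
  expect_error(metaIntegrate(list(LS = list(p = NA_real_))), "no rhythm")
})

test_that("time-course analysis recovers a strong simulated rhythm", {
  set.seed(45)
  vals <- NULL
  for (tt in grid16) {
    mu <- 100 + 40 * cos(2 * pi * (tt - 8) / 24)
    vals <- rbind(vals, data.frame(time_h = tt, v = rnorm(20, mu, 25)))
  }
  tc <- timeCourse("count", vals$time_h, vals$v)
  a <- analyzeTimecourse(tc)
  expect_lt(a$rhythm@integrated$p, 0.01)
  expect_lt(abs(a$rhythm@integrated$period_h - 24), 2)
  expect_lt(a$kw@p, 0.01)
  expect_identical(nrow(a$kw@pairwise), 120L)
  expect_s4_class(a$fit, "CosineFit")
  expect_true(all(c("LS", "JTK", "ARS", "integrated", "kruskal-wallis")
                  %in% a$table$record))
  expect_error(analyzeTimecourse(timeCourse("x", c(1, 1, 2, 2),
                                            c(1, 2, 3, 4))), "3 timepoints")
})

test_that("published mean series reproduce the reported periods", {
  for (case in list(list(marker = "GE-1/HEDLS", period = 23.57),
                    list(marker = "DDX6", period = 23.33))) {
    d <- table_series(case$marker)
    a <- analyzeTimecourse(timeCourse("pb_count_norm", d$time_h, d$mean))
    expect_lt(abs(a$rhythm@integrated$period_h - case$period), 1)
  }
})
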