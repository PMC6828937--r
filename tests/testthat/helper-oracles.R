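## Independent brute-force oracles and small fixture builders shared by
## the unit and acceptance tests. These deliberately re-derive results
## with the slowest, most literal algorithm available.

## dense 2-D convolution with a truncated Gaussian kernel and mirror
## reflection at the borders (same reflection rule as the implementation,
## applied per-axis on the full 2-D kernel)
oracle_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r)
        for (dj in -r:r)
          acc <- acc + k2[di + r + 1, dj + r + 1] *
            m[refl(i + di, nr), refl(j + dj, nc)]
      out[i, j] <- acc
    }
  out
}

## explicitly rasterized ball structuring element
oracle_ball <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  g$h <- sqrt(pmax(0, radius^2 - g$dr^2 - g$dc^2))
  g
}

## grayscale opening = erosion (pad +Inf) then dilation (pad -Inf) by the
## rasterized ball, pixel by pixel
oracle_opening <- function(m, radius) {
  se <- oracle_ball(radius)
  nr <- nrow(m); nc <- ncol(m)
  er <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      ii <- i + se$dr; jj <- j + se$dc
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      er[i, j] <- min(m[cbind(ii[ok], jj[ok])] - se$h[ok])
    }
  di <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      ii <- i - se$dr; jj <- j - se$dc
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      di[i, j] <- max(er[cbind(ii[ok], jj[ok])] + se$h[ok])
    }
  di
}

## exhaustive 8-connectivity flood fill
oracle_flood8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0]) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (!di && !dj) next
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && j >= 1 && i <= nr && j <= nc &&
            mask[i, j] && !lab[i, j]) {
          lab[i, j] <- nxt
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

## hand-computed Kruskal-Wallis H on the shared ranking (no ties)
oracle_kw_H <- function(groups) {
  r <- rank(unlist(groups))
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  idx <- split(seq_len(N), rep(seq_along(groups), n))
  rbar <- vapply(idx, function(i) mean(r[i]), 0)
  12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
}

## draw a filled disk into a matrix
draw_disk <- function(m, row, col, radius, value) {
  for (dr in -ceiling(radius):ceiling(radius))
    for (dc in -ceiling(radius):ceiling(radius))
      if (dr^2 + dc^2 <= radius^2) {
        i <- row + dr; j <- col + dc
        if (i >= 1 && j >= 1 && i <= nrow(m) && j <= ncol(m))
          m[i, j] <- value
      }
  m
}

## small noiseless scene: 5 well-separated spots (frozen seed)
five_spot_config <- function() {
  sceneConfig(fieldWPx = 256, fieldHPx = 192,
              countProgram = oscillationProgram(5, 0, 24, 0),
              colocFraction = 1, poissonGain = 0, readNoiseSd = 0,
              nucleiMean = 0, nucleiSd = 0, rngSeed = 4L)
}

## compact noisy scene for fast field-level tests
small_config <- function(seed = 7L, ...) {
  args <- list(fieldWPx = 344, fieldHPx = 260,
               countProgram = oscillationProgram(30, 10, 24, 8),
               nucleiMean = 4, nucleiSd = 1.5, rngSeed = seed)
  do.call(sceneConfig, utils::modifyList(args, list(...)))
}

table_series <- function(marker) {
  tab <- pbNumberSeries()
  tab[tab$marker == marker, c("time_h", "mean")]
}
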