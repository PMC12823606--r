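# Independent oracles used to validate the package's implementations.
# Each is written as a direct, unoptimized transcription of the defining
# computation and shares no code path with the functions under test.

# Between-class-variance maximizer by explicit search over every histogram
# cut, recomputing class means from scratch at each cut.
oracle_otsu <- function(values, bins = 256L, range = c(0, 2)) {
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  centers <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):bins] * centers[(k + 1):bins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1]
}

# Between-class variance of the cut at a given threshold (same binning as
# the oracle); used to verify that two thresholds are equivalent maximizers
# when the variance surface has a floating-point-level plateau.
oracle_bcv_at <- function(values, thr, bins = 256L, range = c(0, 2)) {
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  centers <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  lo <- centers <= thr
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(-Inf)
  mu0 <- sum(counts[lo] * centers[lo]) / n0
  mu1 <- sum(counts[!lo] * centers[!lo]) / n1
  n0 * n1 * (mu0 - mu1)^2
}

# TRUE when `thr` attains the oracle's maximal between-class variance (up to
# floating-point ties on the plateau).
expect_otsu_equivalent <- function(values) {
  t_mine <- otsu_threshold(values)
  t_oracle <- oracle_otsu(values)
  if (isTRUE(all.equal(t_mine, t_oracle))) {
    testthat::expect_equal(t_mine, t_oracle)
  } else {
    testthat::expect_equal(oracle_bcv_at(values, t_mine),
                           oracle_bcv_at(values, t_oracle),
                           tolerance = 1e-9)
  }
  invisible(t_mine)
}

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled sample to the two groups.
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  p <- 2 * min(mean(all_u <= u_obs + 1e-9), mean(all_u >= u_obs - 1e-9))
  list(statistic = u_obs, p_value = min(p, 1))
}

# Optimal contiguous partition of sorted 1-D data into k clusters by
# within-cluster sum-of-squares dynamic programming; labels returned in the
# original order, numbered by ascending cluster mean.
oracle_dp_cluster <- function(values, k) {
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {  # within-SSE of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) for (i in m:j) {
    v <- cost[m - 1, i - 1] + sse(i, j)
    if (v < cost[m, j] - 1e-12) { cost[m, j] <- v; cut[m, j] <- i }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  for (m in k:2) bounds[m] <- cut[m, bounds[m + 1]] - 1L
  labels_sorted <- integer(n)
  for (m in 1:k) labels_sorted[(bounds[m] + 1):bounds[m + 1]] <- m
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

# Spearman correlation from first principles: mid-ranks + explicit Pearson
# product-moment formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Dense-grid second derivative of an analytic function, averaged over the
# grid points of a band (step 1000x finer than the acquisition grid).
oracle_second_derivative_mean <- function(f, band, grid = make_default_grid()) {
  pts <- grid[grid >= band[1] & grid <= band[2]]
  h <- 0.005
  mean(sapply(pts, function(l) (f(l - h) - 2 * f(l) + f(l + h)) / h^2))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Small analytic fixture spectra on the default grid.
flat_spectrum <- function(value = 0.3) spectrum(rep(value, 100))
linear_spectrum <- function(a = 0.001, b = 0.1) {
  g <- make_default_grid()
  spectrum(a * g + b, g)
}
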