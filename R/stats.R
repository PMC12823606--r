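#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); thin,
#' validated front end to `stats::cor(method = "spearman")`.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return Correlation in [-1, 1].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("Spearman correlation needs at least 3 paired values")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("Spearman correlation undefined: zero rank variance")
  stats::cor(x, y, method = "spearman")
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The U statistic is reported for the first sample. For small tie-free
#' samples (`min(n1, n2) <= 8`) the exact null distribution of U is used
#' (two-sided p as twice the smaller tail, capped at 1); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples, both non-empty.
#' @param exact_max largest `min(n1, n2)` for which the exact distribution
#'   is used (tie-free data only).
#' @return List with `statistic` (U for `a`), `p_value`, `n = c(n1, n2)`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(n1, n2) <= exact_max) {
    # exact null distribution of U (tie-free)
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) return(list(statistic = u, p_value = 1,
                                n = c(n1, n2), method = "normal_approx"))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = u, p_value = min(p, 1), n = c(n1, n2), method = method)
}

#' Omnibus normality test (skewness + kurtosis)
#'
#' D'Agostino-Pearson K-squared test: the sample skewness and kurtosis are
#' each transformed to approximate standard normal deviates (D'Agostino's
#' skewness transform; Anscombe-Glynn's kurtosis transform) and
#' `K2 = Z_skew^2 + Z_kurt^2` is referred to a chi-square distribution with
#' 2 degrees of freedom. Below `n = 20` the approximation is weak and the
#' result is flagged unreliable (attribute + warning); `n < 8` is an error.
#'
#' @param values numeric sample.
#' @return List with `statistic` (K2), `p_value`, `n`, `method`; attribute
#'   `reliable` is `FALSE` for `n < 20`.
#' @export
normality_omnibus <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) stop("omnibus normality test requires n >= 8")
  if (stats::var(x) == 0) stop("normality test undefined for constant input")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  out <- list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
              n = n, method = "dagostino_pearson_k2")
  if (n < 20L) {
    warning("normality omnibus with n < 20 is unreliable")
    attr(out, "reliable") <- FALSE
  } else attr(out, "reliable") <- TRUE
  out
}

#' Minimum detectable correlation (Fisher-z power analysis)
#'
#' The smallest population correlation detectable with two-sided level
#' `alpha` and the given power from `n` paired observations, via the Fisher
#' z transform: `tanh((z[1 - alpha/2] + z[power]) / sqrt(n - 3))`. With the
#' study's cohort size (n = 58, alpha = 0.05, power = 0.80) this evaluates
#' to 0.36.
#'
#' @param n number of pairs (> 3).
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @return Correlation bound in (0, 1).
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.80) {
  if (n <= 3) stop("n must exceed 3")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}
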