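# Independent oracles used to validate the package's computational paths.
# These deliberately avoid the package's internal algorithms: rigidity is
# evaluated by dense quadrature + lm() over a dense grid of window starts,
# level variance by direct counting over a dense grid, and reference
# distributions come from their closed-form CDFs.

# Brute-force spectral rigidity: dense grid of window starts, each window
# evaluated by least-squares (lm) on a dense lambda quadrature grid.
oracle_delta3 <- function(e, L, n_starts = 1500L, n_quad = 600L) {
  e <- sort(e)
  cs <- seq(min(e), max(e) - L, length.out = n_starts)
  vals <- vapply(cs, function(c0) {
    lam <- seq(c0, c0 + L, length.out = n_quad)
    eta <- findInterval(lam, e)       # levels <= lambda
    fit <- stats::lm(eta ~ lam)
    mean(stats::residuals(fit)^2)
  }, numeric(1))
  mean(vals)
}

# Brute-force level number variance: dense c grid, half-open counting.
oracle_sigma2 <- function(e, L, n_starts = 20000L) {
  e <- sort(e)
  cs <- seq(min(e), max(e) - L, length.out = n_starts)
  cnt <- vapply(cs, function(c0) sum(e >= c0 & e < c0 + L), numeric(1))
  mean(cnt^2) - mean(cnt)^2
}

# Closed-form reference CDFs.
semicircle_cdf <- function(x) {
  x <- pmin(pmax(x, -sqrt(2)), sqrt(2))
  0.5 + (x * sqrt(pmax(2 - x^2, 0)) + 2 * asin(pmin(pmax(x / sqrt(2), -1), 1))) / (2 * pi)
}
wigner_cdf <- function(s) 1 - exp(-pi * s^2 / 4)
exp1_cdf <- function(x) 1 - exp(-pmax(x, 0))

# Kolmogorov-Smirnov distance between a sample and a CDF.
ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  theo <- cdf(x)
  max(abs(seq_len(n) / n - theo), abs((seq_len(n) - 1) / n - theo))
}

# Direct N x N correlation-eigenvalue oracle.
oracle_corr_eigs <- function(x) {
  eigen(stats::cor(t(x)), symmetric = TRUE, only.values = TRUE)$values
}

# Midpoint-threshold oracle for the two-cluster log-eigenvalue split.
oracle_split_count_above <- function(values, midpoint_log) {
  sum(log(values) > midpoint_log)
}

# Small random voxel x time matrix.
rand_ts <- function(N, t, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(N * t), N, t)
}
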