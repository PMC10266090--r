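# Eigenvalue extraction, trimming and unfolding for voxelwise correlation
# matrices, plus reference-ensemble simulators used for validation.

#' Eigenvalues of the voxelwise Pearson correlation matrix
#'
#' Computes the eigenvalues of the N x N correlation matrix of the rows of an
#' N x t timeseries matrix without ever forming the N x N matrix. Writing Y for
#' the row-standardized data, the correlation matrix is (t-1)^{-1} Y Y', whose
#' nonzero eigenvalues equal those of the small t x t matrix (t-1)^{-1} Y' Y.
#' Because each row of Y is centered, at most t - 1 eigenvalues are nonzero;
#' cost and memory scale with t^2, never N^2.
#'
#' @param x numeric matrix, N voxels (rows) by t volumes (columns); every row
#'   must be non-constant.
#' @return an [eig_spectrum] with `origin = "correlation"`, sorted ascending.
#'   When `t < N` it has length `t` (the nonzero part of the N-spectrum plus
#'   the structural zero); the `matrix_dim` attribute records N for
#'   precision-threshold purposes.
#' @export
#' @examples
#' x <- matrix(rnorm(400), nrow = 40)   # 40 voxels, 10 volumes
#' ev <- correlation_eigenvalues(x)
#' sum(ev > precision_threshold(ev))    # t - 1 = 9
correlation_eigenvalues <- function(x) {
  x <- as_timeseries_matrix(x)
  N <- nrow(x); tt <- ncol(x)
  s <- row_sds(x)
  if (any(s == 0)) stop("degenerate voxel: constant timeseries in row(s) ",
                        paste(utils::head(which(s == 0), 5L), collapse = ", "))
  if (tt >= N) {
    warning("t >= N: falling back to direct N x N correlation eigendecomposition")
    ev <- eigen(stats::cor(t(x)), symmetric = TRUE, only.values = TRUE)$values
  } else {
    Y <- (x - rowMeans(x)) / s
    small <- crossprod(Y) / (tt - 1)   # t x t
    ev <- eigen(small, symmetric = TRUE, only.values = TRUE)$values
  }
  new_eig_spectrum(ev, origin = "correlation", matrix_dim = N)
}

#' Numerical-precision threshold for near-zero eigenvalues
#'
#' The larger of two standard floating-point error bounds: the matrix-rank
#' convention `n * eps * max(|lambda|)` and the symmetric-eigenproblem bound
#' `eps * ||lambda||_2`, where `n` is the dimension of the source matrix.
#'
#' @param values numeric vector of eigenvalues (or an [eig_spectrum]).
#' @param n_dim source-matrix dimension; defaults to the `matrix_dim`
#'   attribute when present, else `length(values)`.
#' @return scalar threshold.
#' @export
precision_threshold <- function(values, n_dim = NULL) {
  if (is.null(n_dim)) {
    n_dim <- attr(values, "matrix_dim")
    if (is.null(n_dim)) n_dim <- length(values)
  }
  v <- as.numeric(values)
  eps <- .Machine$double.eps
  max(n_dim * eps * max(abs(v)), eps * sqrt(sum(v^2)))
}

# Exact 1-D 2-means on sorted values: returns the split index j minimizing
# within-cluster sum of squares for clusters v[1:j], v[(j+1):n].
split_two_means <- function(v) {
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  j <- seq_len(n - 1L)
  ss_lo <- cs2[j] - cs[j]^2 / j
  nj <- n - j
  ss_hi <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / nj
  which.min(ss_lo + ss_hi)
}

#' Trim an eigenvalue spectrum
#'
#' Four trimming variants applied before unfolding:
#' \describe{
#'   \item{none}{identity.}
#'   \item{precision}{removes eigenvalues below [precision_threshold()], i.e.
#'     values indistinguishable from zero at floating-point precision.}
#'   \item{largest}{after precision trimming, splits the natural logarithms of
#'     the eigenvalues into two clusters by exact one-dimensional 2-means and
#'     removes the cluster with the larger mean (the few large outlying
#'     eigenvalues).}
#'   \item{middle}{applies the largest trim and additionally removes the same
#'     number of eigenvalues from the lower end of the precision-trimmed
#'     spectrum (the threshold is reflected).}
#' }
#'
#' If the 2-means split is degenerate (all log-eigenvalues equal) or would
#' remove more than half of the levels, the precision-trimmed spectrum is
#' returned unchanged with a warning: over-aggressive trims are precisely what
#' these procedures are meant to avoid.
#'
#' @param spec an [eig_spectrum] (or numeric vector).
#' @param how one of `"none"`, `"precision"`, `"largest"`, `"middle"`.
#' @return an [eig_spectrum]; always a subsequence of the input.
#' @export
trim_eigs <- function(spec, how = c("none", "precision", "largest", "middle")) {
  how <- match.arg(how)
  if (length(spec) == 0L) stop("empty spectrum")
  if (!inherits(spec, "eig_spectrum")) spec <- eig_spectrum(spec)
  if (how == "none") {
    attr(spec, "trim") <- "none"
    return(spec)
  }
  v <- as.numeric(spec)
  n_dim <- attr(spec, "matrix_dim")
  thr <- precision_threshold(v, n_dim)
  keep <- v >= thr
  if (!any(keep)) stop("empty spectrum after trim")
  pv <- v[keep]
  if (how == "precision")
    return(new_eig_spectrum(pv, origin = attr(spec, "origin"),
                            matrix_dim = n_dim, trim = "precision"))

  if (length(pv) < 10L)
    stop("largest/middle trimming needs >= 10 eigenvalues after precision trimming")
  lv <- log(pv)
  if (max(lv) - min(lv) < sqrt(.Machine$double.eps)) {
    warning("degenerate 2-means (all log-eigenvalues equal): no trim applied")
    return(new_eig_spectrum(pv, origin = attr(spec, "origin"),
                            matrix_dim = n_dim, trim = "precision"))
  }
  j <- split_two_means(lv)          # upper cluster = pv[(j+1):n], larger mean
  n_top <- length(pv) - j
  frac <- if (how == "largest") n_top else 2L * n_top
  if (n_top == 0L || frac > length(pv) / 2) {
    warning("largest-trim would remove none or > 50% of levels: no trim applied")
    return(new_eig_spectrum(pv, origin = attr(spec, "origin"),
                            matrix_dim = n_dim, trim = "precision"))
  }
  out <- if (how == "largest") pv[seq_len(j)] else pv[(n_top + 1L):j]
  if (length(out) == 0L) stop("empty spectrum after trim")
  new_eig_spectrum(out, origin = attr(spec, "origin"),
                   matrix_dim = n_dim, trim = how)
}

#' Unfold an eigenvalue spectrum
#'
#' Maps a sorted spectrum to levels with unit mean spacing by smoothing the
#' spectral staircase: after trimming, a degree-`degree` polynomial p is
#' least-squares fitted to the points (lambda_i, i) — the empirical cumulative
#' level count — and the unfolded levels are e_i = p(lambda_i). By
#' construction the spacings d_i = e_{i+1} - e_i then average approximately 1,
#' which makes fluctuation statistics comparable across systems.
#'
#' @param spec an [eig_spectrum] or numeric vector.
#' @param degree polynomial degree; the standard analysis grid uses 3, 5, 7, 9.
#' @param how trimming method passed to [trim_eigs()].
#' @return an `unfolded_spectrum` (sorted numeric vector with attributes
#'   `degree`, `trim`, and `nonmonotone` — set when the fitted polynomial was
#'   not monotone over the spectrum and the outputs were re-sorted).
#' @export
#' @examples
#' u <- unfold(eig_spectrum(1:200), degree = 5)
#' mean(spacings(u))   # ~ 1
unfold <- function(spec, degree = 5L, how = "none") {
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  tr <- trim_eigs(spec, how)
  lam <- as.numeric(tr)
  n <- length(lam)
  if (n <= degree + 1L)
    stop("spectrum too short after trimming for requested polynomial degree")
  if (length(unique(lam)) <= degree)
    stop("too few distinct eigenvalues for requested polynomial degree")
  fit <- stats::lm(idx ~ stats::poly(lam, degree),
                   data = data.frame(idx = seq_len(n), lam = lam))
  e <- stats::fitted(fit)
  nonmono <- any(diff(e) < 0)
  new_unfolded_spectrum(e, degree = degree, trim = attr(tr, "trim"),
                        nonmonotone = nonmono)
}

#' Simulate a Gaussian orthogonal ensemble spectrum
#'
#' Eigenvalues of (G + G')/2 with G an n x n matrix of iid standard normals
#' (off-diagonal variance 1/2 after symmetrization, diagonal variance 1).
#' GOE spectra show strong level repulsion and serve as the rigid reference
#' ensemble for the spectral observables.
#'
#' @param n matrix dimension.
#' @param seed integer seed; identical seeds give identical spectra.
#' @return an [eig_spectrum] with `origin = "goe"`, sorted ascending.
#' @export
simulate_goe <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  with_seed(seed, {
    G <- matrix(stats::rnorm(n * n), n, n)
    S <- (G + t(G)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    new_eig_spectrum(ev, origin = "goe", matrix_dim = n)
  })
}

#' Simulate Poisson (uncorrelated) levels
#'
#' Cumulative sums of n iid Exponential(1) spacings: an already-unfolded
#' spectrum with unit mean spacing by construction. Poisson levels are the
#' non-rigid reference ensemble, with known limits Delta3(L) = L/15 and
#' Sigma2(L) = L.
#'
#' @param n number of levels (>= 2).
#' @param seed integer seed.
#' @return an `unfolded_spectrum` (degree `NA`, trim `"none"`).
#' @export
simulate_poisson_levels <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  with_seed(seed, {
    e <- cumsum(stats::rexp(n))
    new_unfolded_spectrum(e, degree = NA_integer_, trim = "none")
  })
}
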