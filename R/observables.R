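# Spectral rigidity and level number variance with Monte-Carlo convergence
# control over window starting points.

new_observable_curve <- function(kind, L_grid, values, n_centers, converged, tol) {
  structure(
    data.frame(L = L_grid, value = values, n_centers = n_centers,
               converged = converged),
    kind = kind, tol = tol,
    class = c("observable_curve", "data.frame"))
}

#' @export
print.observable_curve <- function(x, ...) {
  cat(sprintf("<observable_curve> kind = %s, %d L values, tol = %g\n",
              attr(x, "kind"), nrow(x), attr(x, "tol")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Shared Monte-Carlo driver: draws window starts c uniformly on
# [e_1, e_n - L] in blocks and stops once the estimated standard error of
# `statistic` over the accumulated sample drops below `tol` (relative to the
# current value), subject to min/max center counts. `sampler(starts)` maps
# starts to per-window raw values; `stderr_fn` estimates the Monte-Carlo
# standard error of the statistic from the sample.
mc_converge <- function(e, L, sampler, statistic, stderr_fn, tol, block,
                        min_centers, max_centers) {
  lo <- e[1L]; hi <- e[length(e)] - L
  if (hi <= lo) stop("window exceeds spectrum: L >= spectrum span")
  acc <- numeric(0)
  converged <- FALSE
  while (length(acc) < max_centers) {
    starts <- stats::runif(block, lo, hi)
    acc <- c(acc, sampler(starts))
    if (length(acc) >= min_centers) {
      cur <- statistic(acc)
      se <- stderr_fn(acc)
      if (se <= tol * max(abs(cur), tol)) {
        converged <- TRUE
        break
      }
    }
  }
  list(value = statistic(acc), n_centers = length(acc), converged = converged)
}

# Standard-error estimators: for a sample mean, sd/sqrt(m); for a population
# variance, sqrt((m4 - s^4) / m) from the fourth central moment.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
se_var <- function(x) {
  m <- length(x)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  m4 <- mean((x - mu)^4)
  sqrt(max(m4 - s2^2, 0) / m)
}

check_observable_pre <- function(e, L_grid) {
  if (length(e) < max(L_grid) + 10)
    stop("spectrum too short: need n >= max(L_grid) + 10")
  if (any(L_grid <= 0)) stop("L_grid must be positive")
  span <- e[length(e)] - e[1L]
  if (any(L_grid >= span)) stop("window exceeds spectrum: L >= spectrum span")
}

#' Spectral rigidity Delta3(L)
#'
#' For each window length L, averages over Monte-Carlo window starts c drawn
#' uniformly from \[e_1, e_n - L\]: within each window the least-squares line
#' A*lambda + B is fitted to the staircase eta(lambda) (number of unfolded
#' levels <= lambda) and the mean squared residual (1/L) * integral over
#' \[c, c+L\] is evaluated exactly by piecewise integration over the step
#' intervals. Small values mean a rigid, locally regular spectrum; Poisson
#' levels give L/15, GOE levels grow only logarithmically.
#'
#' Window starts are sampled in blocks until the estimated Monte-Carlo
#' standard error of the running mean drops below `tol` (relative to the
#' current value), with at least `min_centers` and at most `max_centers`
#' starts; the achieved center count and convergence flag are recorded.
#'
#' @param unf an `unfolded_spectrum` (see [unfold()]) or sorted numeric vector
#'   of unfolded levels.
#' @param L_grid positive window lengths (default 1..20).
#' @param tol relative convergence tolerance (target standard error of the
#'   estimate, as a fraction of its value).
#' @param block number of window starts per convergence-check block.
#' @param min_centers,max_centers bounds on the total number of starts.
#' @param seed optional RNG seed for the window starts.
#' @return an `observable_curve` data frame with columns `L`, `value`,
#'   `n_centers`, `converged`.
#' @export
spectral_rigidity <- function(unf, L_grid = 1:20, tol = 0.01, block = 128L,
                              min_centers = 4096L, max_centers = 1e5,
                              seed = NULL) {
  e <- sort(as.numeric(unf))
  check_observable_pre(e, L_grid)
  with_seed(seed, {
    res <- lapply(L_grid, function(L) {
      mc_converge(e, L,
                  sampler = function(starts) rigidity_windows(e, starts, L),
                  statistic = mean, stderr_fn = se_mean,
                  tol = tol, block = block,
                  min_centers = min_centers, max_centers = max_centers)
    })
    new_observable_curve("rigidity", L_grid,
                         vapply(res, `[[`, 0, "value"),
                         vapply(res, `[[`, 0L, "n_centers"),
                         vapply(res, `[[`, TRUE, "converged"),
                         tol)
  })
}

#' Level number variance Sigma2(L)
#'
#' For each window length L, draws Monte-Carlo window starts c uniformly from
#' \[e_1, e_n - L\], counts the unfolded levels in the half-open window
#' \[c, c+L), and returns the variance of the count:
#' Sigma2(L) = <eta^2> - <eta>^2. Poisson levels give Sigma2(L) = L; rigid
#' (GOE-like) spectra grow only logarithmically. Convergence control is as in
#' [spectral_rigidity()], applied to the running variance (standard error
#' estimated from the fourth central moment of the counts).
#'
#' @inheritParams spectral_rigidity
#' @return an `observable_curve` data frame.
#' @export
level_variance <- function(unf, L_grid = 1:20, tol = 0.01, block = 128L,
                           min_centers = 4096L, max_centers = 1e5,
                           seed = NULL) {
  e <- sort(as.numeric(unf))
  check_observable_pre(e, L_grid)
  pop_var <- function(x) mean(x^2) - mean(x)^2
  with_seed(seed, {
    res <- lapply(L_grid, function(L) {
      mc_converge(e, L,
                  sampler = function(starts) as.numeric(window_counts(e, starts, L)),
                  statistic = pop_var, stderr_fn = se_var,
                  tol = tol, block = block,
                  min_centers = min_centers, max_centers = max_centers)
    })
    new_observable_curve("level_variance", L_grid,
                         vapply(res, `[[`, 0, "value"),
                         vapply(res, `[[`, 0L, "n_centers"),
                         vapply(res, `[[`, TRUE, "converged"),
                         tol)
  })
}
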