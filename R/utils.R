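#' @useDynLib rmtfc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd median quantile density predict rexp rnorm runif lm fitted poly
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate an N (voxels) x t (volumes) timeseries matrix.
as_timeseries_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 3L)
    stop("timeseries matrix needs N >= 2 voxels and t >= 3 volumes")
  if (anyNA(x)) stop("timeseries matrix contains missing values")
  x
}

row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
}
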