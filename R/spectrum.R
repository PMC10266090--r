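# S3 containers for eigenvalue spectra and unfolded spectra.

new_eig_spectrum <- function(values, origin = c("correlation", "goe", "poisson", "manual"),
                             matrix_dim = length(values), trim = "none") {
  origin <- match.arg(origin)
  values <- as.numeric(values)
  if (is.unsorted(values)) values <- sort(values)
  structure(values,
            origin = origin,
            matrix_dim = as.integer(matrix_dim),
            trim = trim,
            class = "eig_spectrum")
}

#' Construct an eigenvalue spectrum object
#'
#' Wraps a numeric vector of eigenvalues (sorted ascending) together with its
#' provenance: where the spectrum came from and the dimension of the matrix it
#' was extracted from (used by the precision-trimming threshold).
#'
#' @param values numeric vector of eigenvalues (sorted internally).
#' @param origin one of `"correlation"`, `"goe"`, `"poisson"`, `"manual"`.
#' @param matrix_dim dimension of the source matrix; defaults to
#'   `length(values)`.
#' @return an object of class `eig_spectrum` (a sorted numeric vector with
#'   attributes `origin`, `matrix_dim` and `trim`).
#' @export
#' @examples
#' eig_spectrum(c(3, 1, 2), origin = "manual")
eig_spectrum <- function(values, origin = "manual", matrix_dim = length(values)) {
  new_eig_spectrum(values, origin = origin, matrix_dim = matrix_dim)
}

#' @export
print.eig_spectrum <- function(x, ...) {
  cat(sprintf("<eig_spectrum> n = %d, origin = %s, trim = %s, range [%.4g, %.4g]\n",
              length(x), attr(x, "origin"), attr(x, "trim"),
              min(x), max(x)))
  invisible(x)
}

new_unfolded_spectrum <- function(values, degree, trim, nonmonotone = FALSE) {
  values <- sort(as.numeric(values))
  structure(values,
            degree = degree,
            trim = trim,
            nonmonotone = nonmonotone,
            class = "unfolded_spectrum")
}

#' @export
print.unfolded_spectrum <- function(x, ...) {
  d <- diff(unclass(x))
  cat(sprintf("<unfolded_spectrum> n = %d, degree = %s, trim = %s, mean spacing = %.4f%s\n",
              length(x), format(attr(x, "degree")), attr(x, "trim"),
              mean(d), if (isTRUE(attr(x, "nonmonotone"))) " [non-monotone fit, sorted]" else ""))
  invisible(x)
}

#' Spacings of an unfolded spectrum
#'
#' @param x an `unfolded_spectrum`.
#' @return numeric vector `d_i = e_{i+1} - e_i` of length `n - 1`.
#' @export
spacings <- function(x) {
  diff(as.numeric(x))
}
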