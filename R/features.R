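# The feature catalog: eigenvalue features, RMT features, smoothed variants,
# concatenated combinations, slices, normalization and the baseline
# timeseries reductions.

#' Catalog of predictive features
#'
#' The full set of 34 feature identifiers, grouped coarsely (`eigs`, `rmt`,
#' `tseries`) and finely. 24 are eigenfeatures (derived from the correlation
#' spectrum), 10 are baseline timeseries reductions. In combined identifiers
#' `+` denotes concatenation.
#'
#' @return a data frame with columns `coarse`, `fine`, `feature_id` (34 rows).
#' @export
#' @examples
#' table(feature_catalog()$coarse)
feature_catalog <- function() {
  rows <- rbind(
    c("eigs", "eigs",        "eigs"),
    c("eigs", "eigs max",    "eigsminmax10"),
    c("eigs", "eigs max",    "eigsminmax20"),
    c("eigs", "eigs max",    "eigsminmax5"),
    c("eigs", "eigs middle", "eigsmiddle10"),
    c("eigs", "eigs middle", "eigsmiddle20"),
    c("eigs", "eigs middle", "eigsmiddle40"),
    c("eigs", "eigs smooth", "eigs + eigs_smooth"),
    c("eigs", "eigs smooth", "eigs + savgol"),
    c("eigs", "eigs smooth", "eigs_savgol"),
    c("eigs", "eigs smooth", "eigs_smooth"),
    c("rmt",  "rmt + eigs",  "eigs + levelvar"),
    c("rmt",  "rmt + eigs",  "eigs + rigidity"),
    c("rmt",  "rmt + eigs",  "eigs + rigidity + levelvar"),
    c("rmt",  "rmt + eigs",  "eigs + unfolded"),
    c("rmt",  "rmt + eigs",  "eigs + unfolded + levelvar"),
    c("rmt",  "rmt + eigs",  "eigs + unfolded + rigidity"),
    c("rmt",  "rmt only",    "levelvar"),
    c("rmt",  "rmt only",    "rigidity"),
    c("rmt",  "rmt only",    "rigidity + levelvar"),
    c("rmt",  "rmt only",    "unfolded"),
    c("rmt",  "rmt only",    "unfolded + levelvar"),
    c("rmt",  "rmt only",    "unfolded + rigidity"),
    c("rmt",  "rmt only",    "unfolded + rigidity + levelvar"),
    c("tseries", "location", "T-max"),
    c("tseries", "location", "T-mean"),
    c("tseries", "location", "T-med"),
    c("tseries", "location", "T-min"),
    c("tseries", "location", "T-p05"),
    c("tseries", "location", "T-p95"),
    c("tseries", "scale",    "T-iqr"),
    c("tseries", "scale",    "T-rng"),
    c("tseries", "scale",    "T-rrng"),
    c("tseries", "scale",    "T-std"))
  data.frame(coarse = rows[, 1], fine = rows[, 2], feature_id = rows[, 3],
             stringsAsFactors = FALSE)
}

#' Slice specification
#'
#' A contiguous slice of a feature vector: the full vector, the first (`min`)
#' or last (`max`) 5/10/20 percent, or the middle 10/20/40 percent. Exactly
#' ten combinations are valid.
#'
#' @param region one of `"full"`, `"max"`, `"min"`, `"mid"`.
#' @param fraction slice size as a fraction; `1` for `full`, one of
#'   `0.05, 0.10, 0.20` for `max`/`min`, one of `0.10, 0.20, 0.40` for `mid`.
#' @return a list of class `slice_spec` with elements `region`, `fraction`.
#' @export
slice_spec <- function(region = c("full", "max", "min", "mid"), fraction = NULL) {
  region <- match.arg(region)
  valid <- switch(region,
                  full = 1,
                  max = c(0.05, 0.10, 0.20),
                  min = c(0.05, 0.10, 0.20),
                  mid = c(0.10, 0.20, 0.40))
  if (is.null(fraction)) fraction <- valid[1L]
  if (!any(abs(fraction - valid) < 1e-12))
    stop("invalid fraction ", fraction, " for region '", region, "'")
  structure(list(region = region, fraction = fraction), class = "slice_spec")
}

#' All ten slice specifications
#'
#' @return a list of the 10 valid [slice_spec()] objects, in canonical order
#'   (full, then max/min/mid by increasing fraction).
#' @export
slice_specs <- function() {
  out <- list(slice_spec("full"))
  for (r in c("max", "min")) for (f in c(0.05, 0.10, 0.20))
    out[[length(out) + 1L]] <- slice_spec(r, f)
  for (f in c(0.10, 0.20, 0.40))
    out[[length(out) + 1L]] <- slice_spec("mid", f)
  out
}

#' @export
format.slice_spec <- function(x, ...) {
  if (x$region == "full") "full" else sprintf("%s-%g", x$region, x$fraction)
}

#' @export
print.slice_spec <- function(x, ...) {
  cat("<slice_spec>", format(x), "\n")
  invisible(x)
}

#' Slice a feature vector
#'
#' Positional slicing of a (typically sorted) feature vector. `max` takes the
#' last `ceiling(f * n)` elements, `min` the first `ceiling(f * n)`, `mid` a
#' centered run of `k = ceiling(f * n)` elements starting at index
#' `floor((n - k) / 2) + 1`. Ceiling rounding guarantees a non-empty slice.
#'
#' @param values numeric vector (non-empty).
#' @param slice a [slice_spec()].
#' @return the sliced numeric vector.
#' @export
#' @examples
#' slice_values(1:100, slice_spec("max", 0.20))   # 81..100
slice_values <- function(values, slice) {
  n <- length(values)
  if (n == 0L) stop("empty slice: cannot slice an empty vector")
  if (slice$region == "full") return(values)
  k <- ceiling(slice$fraction * n)
  switch(slice$region,
         max = values[(n - k + 1L):n],
         min = values[seq_len(k)],
         mid = {
           start <- floor((n - k) / 2) + 1L
           values[start:(start + k - 1L)]
         })
}

#' Smooth a feature vector
#'
#' Uniform smoothing is a centered moving average with truncated (shrinking)
#' windows at the boundaries, so length is preserved. Savitzky-Golay smoothing
#' fits a local least-squares polynomial of order `min(2, window - 1)`;
#' windows must be odd for `savgol`. A window of 1 is the identity.
#'
#' @param values numeric vector.
#' @param kind `"uniform"` or `"savgol"`.
#' @param window window size; eigenfeatures use 3, 5, 7, 9, baseline
#'   reductions use 1, 2, 4, 8, 16 (uniform only).
#' @return smoothed vector, same length as the input.
#' @export
#' @examples
#' smooth_values(c(1, 2, 3, 4, 5), "uniform", 3)   # 1.5 2 3 4 4.5
smooth_values <- function(values, kind = c("uniform", "savgol"), window) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  n <- length(values)
  if (window > n) stop("window exceeds vector length")
  if (window < 1L) stop("window must be >= 1")
  if (window == 1L) return(values)
  if (kind == "uniform") {
    left <- (window - 1L) %/% 2L
    right <- window - 1L - left
    cs <- c(0, cumsum(values))
    i <- seq_len(n)
    lo <- pmax(i - left, 1L)
    hi <- pmin(i + right, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    if (window %% 2L == 0L) stop("savgol window must be odd")
    as.numeric(signal::sgolayfilt(values, p = min(2L, window - 1L), n = window))
  }
}

#' Concatenate component feature vectors
#'
#' Combined features are formed by concatenation: components f1..fn with
#' dimensions p1..pn yield one vector of dimension sum(p_i), in the given
#' order. Any slicing must already have been applied per component.
#'
#' @param features a non-empty list of numeric vectors.
#' @return the concatenated numeric vector.
#' @export
combine_features <- function(features) {
  if (!length(features)) stop("empty feature list")
  unlist(features, use.names = FALSE)
}

#' Normalize a feature matrix for classification
#'
#' Eigenfeatures always get a natural logarithm first (their raw values are
#' exponentially distributed); values at or below zero are clipped to the
#' matrix's precision threshold with a warning. Min-max rescaling, when
#' requested, is fitted on the training rows only and applied to both sets;
#' constant training dimensions map to 0.
#'
#' @param train numeric matrix, training samples x feature dimensions.
#' @param test optional matrix with the same columns (validation fold).
#' @param method `"raw"` (no rescaling) or `"minmax"`.
#' @param is_eigenfeature logical; apply the log transform?
#' @return a list with elements `train` and `test` (NULL if no test given).
#' @export
normalize_features <- function(train, test = NULL,
                               method = c("raw", "minmax"),
                               is_eigenfeature = TRUE) {
  method <- match.arg(method)
  train <- as.matrix(train)
  if (!is.null(test)) test <- as.matrix(test)
  if (is_eigenfeature) {
    clip <- .Machine$double.eps * max(abs(train), 1)
    logc <- function(m) {
      bad <- m <= 0
      if (any(bad)) {
        warning("clipping ", sum(bad), " non-positive eigenfeature value(s) ",
                "to the precision threshold before log")
        m[bad] <- clip
      }
      log(m)
    }
    train <- logc(train)
    if (!is.null(test)) test <- logc(test)
  }
  if (method == "minmax") {
    lo <- apply(train, 2L, min)
    hi <- apply(train, 2L, max)
    rng <- hi - lo
    const <- rng == 0
    if (any(const)) warning("constant feature dimension(s) under minmax mapped to 0")
    rng[const] <- 1
    scale01 <- function(m) {
      m <- sweep(m, 2L, lo, "-")
      m <- sweep(m, 2L, rng, "/")
      m[, const] <- 0
      m
    }
    train <- scale01(train)
    if (!is.null(test)) test <- scale01(test)
  }
  list(train = train, test = test)
}

#' Baseline timeseries reductions
#'
#' Reduces the N x t voxel matrix along the voxel dimension, one statistic per
#' time point, yielding a t-dimensional feature, then applies uniform
#' smoothing of width `window`. `T-mean` is the usual global mean signal;
#' `T-rng` is max - min, `T-rrng` the 95th minus the 5th percentile, per time
#' point. Percentiles use linear interpolation between order statistics.
#'
#' @param ts N x t numeric matrix (voxels x volumes).
#' @param stat one of `"mean"`, `"median"`, `"max"`, `"min"`, `"p95"`,
#'   `"p05"`, `"std"`, `"range"`, `"robust_range"`, `"iqr"`.
#' @param window uniform smoothing window, one of 1, 2, 4, 8, 16.
#' @return numeric vector of length t.
#' @export
timeseries_reduction <- function(ts, stat = c("mean", "median", "max", "min",
                                              "p95", "p05", "std", "range",
                                              "robust_range", "iqr"),
                                 window = 1L) {
  stat <- match.arg(stat)
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  if (nrow(ts) < 2L || ncol(ts) < 1L || anyNA(ts))
    stop("need an N >= 2 voxel matrix without missing values")
  f <- switch(stat,
              mean = colMeans(ts),
              median = apply(ts, 2L, stats::median),
              max = apply(ts, 2L, max),
              min = apply(ts, 2L, min),
              p95 = apply(ts, 2L, stats::quantile, probs = 0.95, names = FALSE),
              p05 = apply(ts, 2L, stats::quantile, probs = 0.05, names = FALSE),
              std = apply(ts, 2L, stats::sd),
              range = apply(ts, 2L, function(v) max(v) - min(v)),
              robust_range = apply(ts, 2L, function(v)
                diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))),
              iqr = apply(ts, 2L, stats::IQR))
  smooth_values(f, "uniform", window)
}

baseline_stat_for_id <- function(id) {
  switch(id,
         "T-mean" = "mean", "T-med" = "median", "T-max" = "max",
         "T-min" = "min", "T-p95" = "p95", "T-p05" = "p05",
         "T-std" = "std", "T-rng" = "range", "T-rrng" = "robust_range",
         "T-iqr" = "iqr",
         stop("unknown baseline feature id: ", id))
}

# Component values for one eigenfeature component name, given the raw
# correlation spectrum. `degree` doubles as the smoothing window for the
# smoothed-eigenvalue components (the shared degree/window grid axis).
eig_component <- function(comp, spec, trim, degree, L_grid, seed, ...) {
  pe <- as.numeric(trim_eigs(spec, "precision"))
  switch(comp,
         "eigs" = pe,
         "eigsminmax5"  = c(slice_values(pe, slice_spec("min", 0.05)),
                            slice_values(pe, slice_spec("max", 0.05))),
         "eigsminmax10" = c(slice_values(pe, slice_spec("min", 0.10)),
                            slice_values(pe, slice_spec("max", 0.10))),
         "eigsminmax20" = c(slice_values(pe, slice_spec("min", 0.20)),
                            slice_values(pe, slice_spec("max", 0.20))),
         "eigsmiddle10" = slice_values(pe, slice_spec("mid", 0.10)),
         "eigsmiddle20" = slice_values(pe, slice_spec("mid", 0.20)),
         "eigsmiddle40" = slice_values(pe, slice_spec("mid", 0.40)),
         "eigs_smooth" = smooth_values(pe, "uniform", degree),
         "eigs_savgol" = ,
         "savgol" = smooth_values(pe, "savgol", degree),
         "unfolded" = as.numeric(unfold(spec, degree = degree, how = trim)),
         "rigidity" = spectral_rigidity(unfold(spec, degree = degree, how = trim),
                                        L_grid = L_grid, seed = seed, ...)$value,
         "levelvar" = level_variance(unfold(spec, degree = degree, how = trim),
                                     L_grid = L_grid, seed = seed, ...)$value,
         stop("unknown feature component: ", comp))
}

#' Compute one catalog feature from a timeseries matrix
#'
#' Dispatches on the feature identifier (see [feature_catalog()]). For
#' combined identifiers (containing `+`), slicing is applied per component
#' before concatenation. RMT components (rigidity, levelvar) are computed on
#' `L_grid` (default 1..20). For smoothed-eigenvalue components, `degree`
#' doubles as the smoothing window (the grid's shared degree/window axis).
#' Parameters irrelevant to an identifier are accepted and ignored.
#'
#' @param ts N x t numeric matrix (voxels x volumes).
#' @param id feature identifier from the catalog.
#' @param trim trimming method for unfolding-based components.
#' @param degree unfolding polynomial degree / smoothing window (3, 5, 7, 9).
#' @param slice a [slice_spec()]; applied per component.
#' @param window baseline smoothing window (baseline identifiers only).
#' @param L_grid window lengths for the spectral observables.
#' @param seed seed for the Monte-Carlo observables.
#' @param ... further arguments (e.g. `tol`, `min_centers`) for
#'   [spectral_rigidity()] / [level_variance()].
#' @return numeric feature vector with attributes `feature_id`, `slice`,
#'   `trim`, `degree`.
#' @export
compute_feature <- function(ts, id, trim = "none", degree = 3L,
                            slice = slice_spec("full"), window = 1L,
                            L_grid = 1:20, seed = 0L, ...) {
  cat_ids <- feature_catalog()$feature_id
  if (!id %in% cat_ids) stop("unknown feature id: ", id)
  if (startsWith(id, "T-")) {
    out <- timeseries_reduction(ts, baseline_stat_for_id(id), window = window)
  } else {
    spec <- correlation_eigenvalues(ts)
    comps <- strsplit(id, " + ", fixed = TRUE)[[1L]]
    vals <- lapply(comps, function(cmp) {
      v <- eig_component(cmp, spec, trim, degree, L_grid, seed, ...)
      if (!length(v)) stop("empty slice")
      slice_values(v, slice)
    })
    out <- combine_features(vals)
  }
  if (!length(out)) stop("empty slice")
  structure(out, feature_id = id, slice = format(slice),
            trim = trim, degree = degree)
}
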