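# Feature catalog, slicing, smoothing, combination, normalization, baselines.

test_that("the catalog has 34 unique ids in the documented groupings", {
  cat34 <- feature_catalog()
  expect_equal(nrow(cat34), 34L)
  expect_equal(anyDuplicated(cat34$feature_id), 0L)
  expect_equal(sum(cat34$coarse == "eigs"), 11L)
  expect_equal(sum(cat34$coarse == "rmt"), 13L)
  expect_equal(sum(cat34$coarse == "tseries"), 10L)
  expect_equal(sum(cat34$fine == "rmt + eigs"), 6L)
  expect_equal(sum(cat34$fine == "rmt only"), 7L)
  row <- cat34[cat34$feature_id == "eigs + unfolded + rigidity", ]
  expect_equal(row$coarse, "rmt")
  expect_equal(row$fine, "rmt + eigs")
})

test_that("slicing follows the ceil-rounding and centering rules", {
  expect_equal(slice_values(1:100, slice_spec("max", 0.20)), 81:100)
  expect_equal(slice_values(1:100, slice_spec("min", 0.05)), 1:5)
  expect_identical(slice_values(1:7, slice_spec("full")), 1:7)
  # n = 20, mid-40%: k = 8 elements at 1-based indices 7..14
  expect_equal(slice_values(1:20, slice_spec("mid", 0.40)), 7:14)
  expect_equal(length(slice_values(1:3, slice_spec("max", 0.05))), 1L)  # ceil
  expect_equal(length(slice_specs()), 10L)
  expect_error(slice_spec("mid", 0.05), "invalid fraction")
})

test_that("slicing is idempotent and min/max slices are disjoint", {
  set.seed(3)
  v <- sort(rnorm(57))
  for (s in slice_specs()) {
    out <- slice_values(v, s)
    expect_identical(slice_values(out, slice_spec("full")), out)
    expect_gte(length(out), 1L)
  }
  for (f in c(0.05, 0.10, 0.20)) {
    lo <- slice_values(seq_along(v), slice_spec("min", f))
    hi <- slice_values(seq_along(v), slice_spec("max", f))
    expect_length(intersect(lo, hi), 0L)
  }
})

test_that("smoothing: identity, constants, hand-computed average, savgol", {
  expect_identical(smooth_values(c(5, 1, 9), "uniform", 1L), c(5, 1, 9))
  expect_equal(smooth_values(rep(3, 10), "uniform", 4L), rep(3, 10))
  expect_equal(smooth_values(rep(3, 11), "savgol", 5L), rep(3, 11))
  expect_equal(smooth_values(c(1, 2, 3, 4, 5), "uniform", 3L),
               c(1.5, 2, 3, 4, 4.5))
  # Savitzky-Golay reproduces low-order polynomials on interior points
  x <- (1:30)^2 + 3 * (1:30) - 2
  sg <- smooth_values(x, "savgol", 7L)
  expect_equal(sg[4:27], x[4:27], tolerance = 1e-8)
  expect_error(smooth_values(1:3, "uniform", 5L), "window")
  expect_error(smooth_values(1:10, "savgol", 4L), "odd")
})

test_that("combination concatenates in order and preserves single components", {
  expect_equal(combine_features(list(1:3, 4:8)), 1:8)
  expect_equal(length(combine_features(list(rnorm(3), rnorm(5)))), 8L)
  v <- rnorm(4)
  expect_equal(combine_features(list(v)), v)
  expect_error(combine_features(list()), "empty")
})

test_that("normalization: log for eigenfeatures, train-fitted minmax bounds", {
  ev <- exp(1:3)
  out <- normalize_features(matrix(ev, 1), method = "raw", is_eigenfeature = TRUE)
  expect_equal(as.numeric(out$train), c(1, 2, 3))
  base <- matrix(c(1, 5, 2, 8), 2)
  out2 <- normalize_features(base, method = "raw", is_eigenfeature = FALSE)
  expect_identical(out2$train, base)                       # baselines: no log
  set.seed(4)
  tr <- matrix(rnorm(40), 10); te <- matrix(rnorm(20), 5)
  nm <- normalize_features(tr, te, method = "minmax", is_eigenfeature = FALSE)
  expect_true(all(nm$train >= 0 & nm$train <= 1))
  expect_true(all(apply(nm$train, 2, min) == 0))
  expect_true(all(apply(nm$train, 2, max) == 1))           # endpoints attained
  cc <- cbind(rnorm(5), rep(2, 5))
  expect_warning(nc <- normalize_features(cc, method = "minmax",
                                          is_eigenfeature = FALSE), "constant")
  expect_true(all(nc$train[, 2] == 0))
  expect_warning(normalize_features(matrix(c(-1, 2, 3), 1), method = "raw",
                                    is_eigenfeature = TRUE), "clipping")
})

test_that("baseline reductions match direct arithmetic and drop to zero", {
  m <- matrix(c(1, 2, 3, 6, 5, 10), nrow = 3, byrow = TRUE)
  expect_equal(timeseries_reduction(m, "mean"), c(3, 6))
  expect_equal(timeseries_reduction(m, "range"), c(4, 8))
  const <- matrix(7, nrow = 5, ncol = 4)
  expect_equal(timeseries_reduction(const, "std"), rep(0, 4))
  set.seed(12)
  u <- matrix(rep(runif(101), 3), ncol = 3)
  p95 <- timeseries_reduction(u, "p95")
  expect_lt(abs(p95[1] - 0.95), 0.07)
  # type-7 interpolation: h = (n - 1) p + 1 = 96 exactly for n = 101, p = .95
  expect_equal(p95[1], sort(u[, 1])[96], tolerance = 1e-10)
})

test_that("baseline reductions are invariant under voxel permutation", {
  set.seed(9)
  m <- matrix(rnorm(50 * 6), 50, 6)
  perm <- sample(50)
  for (stat in c("mean", "median", "max", "min", "p95", "p05", "std",
                 "range", "robust_range", "iqr")) {
    expect_equal(timeseries_reduction(m, stat, window = 2L),
                 timeseries_reduction(m[perm, ], stat, window = 2L))
  }
})

test_that("single features and combinations have the documented dimensions", {
  # fixture with a 100-eigenvalue spectrum: 500 voxels x 101 volumes
  set.seed(31)
  ts <- rand_ts(500, 101)
  expect_length(compute_feature(ts, "eigs"), 100L)
  expect_length(compute_feature(ts, "eigsmiddle20"), 20L)
  expect_length(compute_feature(ts, "eigsminmax5"), 10L)
  # top 20 eigenvalues + top 4 of the 20 rigidity values = 24
  fv <- compute_feature(ts, "eigs + rigidity", trim = "precision", degree = 5L,
                        slice = slice_spec("max", 0.20), seed = 1L,
                        min_centers = 128L, max_centers = 256L)
  expect_length(fv, 24L)
})

test_that("unknown ids and empty slices are rejected", {
  ts <- rand_ts(30, 8, seed = 2)
  expect_error(compute_feature(ts, "notafeature"), "unknown feature id")
})
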