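# Eigenvalue extraction, trimming, unfolding, simulators.

test_that("transpose identity matches the explicit N x N correlation spectrum", {
  set.seed(101)
  for (rep in 1:10) {
    N <- sample(10:60, 1L)
    t <- sample(4:12, 1L)
    if (t >= N) t <- N - 1L
    x <- rand_ts(N, t)
    ev <- correlation_eigenvalues(x)
    direct <- oracle_corr_eigs(x)
    thr <- precision_threshold(direct, N)
    nz_direct <- sort(direct[direct > thr])
    nz_fast <- as.numeric(ev)[as.numeric(ev) > thr]
    expect_equal(length(nz_fast), length(nz_direct))
    expect_lt(max(abs(nz_fast - nz_direct)), 1e-8)
  }
})

test_that("generic N x t input has exactly t - 1 above-threshold eigenvalues", {
  set.seed(7)
  x <- rand_ts(1000, 10)
  ev <- correlation_eigenvalues(x)
  expect_equal(sum(ev > precision_threshold(ev)), 9L)
})

test_that("rank-1 input (all rows proportional) gives single eigenvalue N", {
  base <- c(1, 3, 2, 5, 4, 6)
  x <- outer(seq(0.5, 5, length.out = 20), base)   # 20 voxels, scaled copies
  ev <- correlation_eigenvalues(x)
  nz <- as.numeric(ev)[ev > precision_threshold(ev)]
  expect_equal(nz, 20, tolerance = 1e-10)
})

test_that("constant rows are rejected and t >= N falls back with warning", {
  x <- rand_ts(10, 5, seed = 1)
  x[3, ] <- 2
  expect_error(correlation_eigenvalues(x), "degenerate voxel")
  y <- rand_ts(5, 8, seed = 2)
  expect_warning(ev <- correlation_eigenvalues(y), "falling back")
  expect_equal(length(ev), 5L)
  direct <- sort(oracle_corr_eigs(y))
  expect_equal(as.numeric(ev), direct, tolerance = 1e-10)
})

test_that("trimming: identity, precision zeros, and subsequence invariant", {
  sp <- eig_spectrum(c(0, 0, 1, 2, 3))
  expect_identical(as.numeric(trim_eigs(sp, "none")), as.numeric(sp))
  expect_equal(as.numeric(trim_eigs(sp, "precision")), c(1, 2, 3))
  set.seed(11)
  v <- sort(c(exp(rnorm(60)), exp(rnorm(6, 6, 0.1))))
  for (how in c("none", "precision", "largest", "middle")) {
    out <- as.numeric(trim_eigs(eig_spectrum(v), how))
    expect_true(all(out %in% v))                 # subsequence of input
    expect_true(!is.unsorted(out))
  }
  pt <- trim_eigs(eig_spectrum(v), "precision")
  expect_true(all(as.numeric(pt) >= precision_threshold(v, length(v))))
})

test_that("largest/middle trimming removes the high log-cluster symmetrically", {
  set.seed(42)
  bulk <- exp(rnorm(100, 0, 0.05))
  top <- exp(rnorm(8, 8, 0.05))
  sp <- eig_spectrum(c(bulk, top))
  # oracle: the midpoint between the two log-clusters separates them cleanly
  n_top <- oracle_split_count_above(c(bulk, top), midpoint_log = 4)
  expect_equal(n_top, 8L)
  tl <- trim_eigs(sp, "largest")
  expect_equal(length(tl), 100L)
  expect_true(all(as.numeric(tl) < min(top)))
  tm <- trim_eigs(sp, "middle")
  expect_equal(length(tm), 92L)
  expect_equal(as.numeric(tm), sort(bulk)[9:100], tolerance = 1e-12)
})

test_that("degenerate or destructive 2-means splits fall back with a warning", {
  sp <- eig_spectrum(rep(2, 20))
  expect_warning(out <- trim_eigs(sp, "largest"), "degenerate")
  expect_equal(length(out), 20L)
  # two clusters of equal size: removing the top half would strip 50%+
  sp2 <- eig_spectrum(c(exp(rnorm(10, 0, 0.01)), exp(rnorm(10, 8, 0.01))))
  expect_warning(out2 <- trim_eigs(sp2, "middle"), "50%")
  expect_equal(length(out2), 20L)
})

test_that("unfolding the picket fence is the identity with unit spacings", {
  for (deg in c(3L, 5L, 7L, 9L)) {
    u <- unfold(eig_spectrum(as.numeric(1:200)), degree = deg)
    expect_lt(max(abs(as.numeric(u) - 1:200)), 0.01)
    expect_true(all(abs(spacings(u) - 1) < 0.01))
  }
})

test_that("every unfolded spectrum has mean spacing near one", {
  set.seed(5)
  for (rep in 1:8) {
    x <- rand_ts(300, 60)
    u <- suppressWarnings(
      unfold(correlation_eigenvalues(x),
             degree = sample(c(3, 5, 7, 9), 1L),
             how = sample(c("none", "precision", "largest", "middle"), 1L)))
    expect_gte(mean(spacings(u)), 0.9)
    expect_lte(mean(spacings(u)), 1.1)
  }
})

test_that("unfolding rejects degenerate inputs", {
  expect_error(unfold(eig_spectrum(c(1, 2, 3)), degree = 3), "too short")
  expect_error(unfold(eig_spectrum(rep(c(1, 2), 10)), degree = 5), "distinct")
})

test_that("GOE simulator: determinism, 1x1 case, semicircle law", {
  expect_equal(length(simulate_goe(1, seed = 3)), 1L)
  expect_identical(as.numeric(simulate_goe(50, seed = 9)),
                   as.numeric(simulate_goe(50, seed = 9)))
  expect_error(simulate_goe(0), "positive")
  g <- simulate_goe(1000, seed = 4)
  expect_lt(ks_stat(as.numeric(g) / sqrt(1000), semicircle_cdf), 0.05)
})

test_that("Poisson level simulator: increasing, unit mean spacing, Exp(1) gaps", {
  p <- simulate_poisson_levels(10000, seed = 8)
  expect_true(all(diff(as.numeric(p)) > 0))
  expect_lt(abs(mean(spacings(p)) - 1), 0.05)
  expect_lt(ks_stat(spacings(p), exp1_cdf), 0.05)
  expect_identical(as.numeric(simulate_poisson_levels(100, seed = 1)),
                   as.numeric(simulate_poisson_levels(100, seed = 1)))
})
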