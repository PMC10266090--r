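---
title: "Random-matrix eigenfeatures for functional connectivity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-matrix eigenfeatures for functional connectivity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmtfc)
```

## The problem

A whole-brain fMRI scan yields, after masking to the N non-constant voxels,
an N x t matrix M of BOLD timeseries, with t (the number of volumes) far
smaller than N. The voxelwise functional connectivity — the N x N Pearson
correlation matrix of the rows of M — is a natural representation of the
scan, but is far too large to use directly. Random matrix theory (RMT)
suggests a drastic but principled reduction: keep only the eigenvalues of the
correlation matrix, and summary statistics of their fluctuations. This
package computes that family of "eigenfeatures" and provides a harness for
asking, over a *grid* of defensible analytic choices rather than a single
pipeline, whether any of them carry predictive signal about a binary label
attached to each scan.

## Eigenvalues without the N x N matrix

Because correlation matrices of rank-deficient data have at most t - 1
nonzero eigenvalues, the spectrum can be obtained from the small t x t
matrix instead. Writing Y for the row-standardized data, the correlation
matrix is (t-1)^-1 Y Y', and the nonzero eigenvalues of Y Y' equal those of
Y' Y. `correlation_eigenvalues()` therefore computes the eigendecomposition
of the t x t matrix (t-1)^-1 Y'Y; cost and memory scale with t^2 and never
with N^2. Row centering makes one eigenvalue structurally zero, so a generic
scan yields exactly t - 1 eigenvalues above numerical precision, which the
tests verify against a direct N x N eigendecomposition on small instances.

```{r transpose}
x <- matrix(rnorm(2000 * 30), 2000, 30)   # 2000 voxels, 30 volumes
ev <- correlation_eigenvalues(x)
sum(ev > precision_threshold(ev))          # t - 1 = 29
```

## Trimming

Extreme eigenvalues destabilize the polynomial fit used in unfolding, and
near-zero eigenvalues are numerical artifacts. Four trimming variants are
provided (`trim_eigs()`):

* **none** — identity.
* **precision** — removes eigenvalues below the larger of two standard
  floating-point bounds: the matrix-rank convention `n * eps * max|lambda|`
  and the symmetric-eigenproblem bound `eps * ||lambda||_2`.
* **largest** — the eigenvalues of correlation matrices of strongly
  correlated data grow exponentially, so the split between "bulk" and
  "large" is found on the *logarithms*: a two-cluster 1-D k-means partition
  of the log-eigenvalues, removing the cluster with the larger mean.
* **middle** — the largest trim, reflected: the same number of eigenvalues
  is also removed from the bottom of the precision-trimmed spectrum.

One-dimensional 2-means does not need the usual iterative algorithm: the
optimal partition of sorted values is a contiguous split, so we scan all
n - 1 split points and take the within-cluster sum-of-squares minimizer.
This is exact, deterministic and O(n), removing any dependence on restarts
or seeds. If the split is degenerate (all logs equal) or would remove more
than half the spectrum, the precision-trimmed spectrum is returned with a
warning — over-aggressive trimming is precisely what these procedures exist
to avoid.

## Unfolding

Fluctuation statistics are only comparable between spectra after the
system-specific mean level density is removed. `unfold()` performs the
standard polynomial smoothing of the spectral staircase: a degree-d
polynomial p is least-squares fitted to the points (lambda_i, i), i.e. to
the empirical cumulative level count, and the unfolded levels are
e_i = p(lambda_i). Because p tracks the staircase, the spacings
d_i = e_{i+1} - e_i average approximately 1; the package checks
mean spacing in [0.9, 1.1] for n >= 50 as an invariant. The analysis grid
uses degrees 3, 5, 7 and 9. Orthogonal polynomials are used internally for
numerical conditioning. If the fitted polynomial happens to be non-monotone
over the spectrum (possible for aggressive degrees on short spectra), the
outputs are sorted and the result is flagged `nonmonotone` rather than
failing, since downstream observables only require sorted levels.

On a GOE spectrum this unfolding reproduces the expected universal behavior:
nearest-neighbour spacings follow the Wigner surmise
p(s) = (pi s / 2) exp(-pi s^2 / 4), which the acceptance suite verifies by a
Kolmogorov–Smirnov distance below 0.05 at n = 2000.

## Spectral rigidity and level number variance

Two classical spectral observables summarize the fluctuations of the
unfolded levels over windows of length L (computed for L = 1..20):

* **Spectral rigidity** Delta3(L): the mean squared deviation of the level
  staircase eta(lambda) from its best-fit straight line over a window
  [c, c + L], averaged over window positions c. Within each window the
  least-squares line and the integral of the squared residual are evaluated
  *exactly* by piecewise integration over the step intervals of eta (the
  staircase is piecewise constant, so all moments are closed-form). This
  removes any quadrature knob; the brute-force oracle used in the tests
  instead evaluates the same quantity by dense-grid least squares.
* **Level number variance** Sigma2(L): the variance over c of the number of
  levels in the half-open window [c, c + L). The half-open convention makes
  the picket-fence case exact: every integer-length window of an integer
  lattice contains exactly L levels, so Sigma2 is identically zero.

Reference ensembles anchor both observables: Poisson levels
(`simulate_poisson_levels()`, iid Exponential(1) spacings) have
Delta3(L) = L/15 and Sigma2(L) = L; GOE spectra (`simulate_goe()`) grow only
logarithmically and sit strictly below the Poisson curves for L >= 5. Both
limits are verified in the test suite at n = 10000 (Poisson, 10 seeds) and
n = 5000 (GOE).

### Monte-Carlo convergence

Window starts c are drawn uniformly from [e_1, e_n - L] in blocks
(default 128). Sampling stops when the estimated standard error of the
statistic falls below the requested relative tolerance (default 0.01):
sd/sqrt(m) for the rigidity mean, and the fourth-central-moment formula
sqrt((m4 - s^4)/m) for the count variance. A floor of `min_centers`
(default 4096) guards against stopping on an unluckily quiet early block and
a cap of `max_centers` (default 1e5) bounds the work; the achieved center
count and a convergence flag are recorded on every curve. We chose an
explicit standard-error criterion rather than a block-to-block
running-mean-change heuristic because the latter does not bound the
estimator's error: in our measurements a 1% change criterion left ~3-4%
error in Sigma2, while the standard-error stop brings both observables
within twice the stated tolerance of an exhaustive dense-grid evaluation,
which the test suite checks directly.

## The feature catalog

`feature_catalog()` enumerates 34 features in three coarse groups:

* **eigs** (11): raw sorted eigenvalues; their first-and-last 5/10/20%
  tails (`eigsminmax*`); their middle 10/20/40% (`eigsmiddle*`); uniform
  and Savitzky–Golay smoothed variants and their concatenations with the
  raw values.
* **rmt** (13): unfolded eigenvalues, Delta3 and Sigma2 curves, and
  concatenations among themselves and with the raw eigenvalues.
* **tseries** (10): baseline reductions of M along the voxel axis, one
  value per time point — mean, median, max, min, 5th/95th percentile,
  standard deviation, range, robust range (p95 - p05) and interquartile
  range — optionally smoothed with uniform windows 1, 2, 4, 8, 16.

Combined features concatenate their components; slicing (10 variants: full,
first/last 5/10/20%, middle 10/20/40%) is applied per component *before*
concatenation, with slice sizes rounded up (`ceiling(f * n)`) so no slice is
ever empty — relevant for the 20-point observable curves at 5%. Mid slices
start at `floor((n - k)/2) + 1`. The smoothing window of the smoothed
eigenvalue features rides on the same grid axis as the unfolding degree
(3, 5, 7, 9), mirroring how the analysis grid treats "unfolding/smoothing
degree" as a single factor. Savitzky–Golay uses polynomial order
`min(2, window - 1)` so the window-3 case remains valid; uniform smoothing
truncates (shrinks) its window at the boundaries so length is preserved.

Because eigenvalue features are exponentially distributed, all
eigenfeatures are log-transformed before classification; min–max rescaling
to [0, 1] is optional (the grid's normalization axis) and its statistics
are always fitted on training folds only. Baseline features are never
log-transformed.

## The multiverse harness

The analytic grid (`enumerate_grid()`) crosses 4 preprocessing levels x
2 normalizations x 4 trims x 4 degrees x 10 slices = 1280 points per
eigenfeature, and 4 x 2 x 5 smoothing windows = 40 per baseline feature.
With 24 eigenfeatures, 10 baselines, 6 classifiers and the 11 binary tasks
of the full design, the accounting reproduces 2,053,920 evaluations
(`multiverse_total_evaluations()`).

Each cell is scored by stratified five-fold cross validation
(`crossval_evaluate()`) with a fixed split seed, reporting the fold-mean
AUROC (mAUROC) plus accuracy, adjusted accuracy (accuracy minus the
majority-class proportion of the whole dataset, so positive = better than
majority guessing) and F1. AUROC uses continuous positive-class scores: vote
fractions for k-NN, probabilities for the SVM, random forest and boosted
trees. The classifiers are the library implementations with default
hyperparameters: gradient-boosted trees (xgboost, 100 rounds), random
forest, RBF-kernel SVM, and k-NN with k = 3, 5, 9. Folds are stratified by
class — several realistic tasks are imbalanced enough that unstratified
splits can lose a class — and the split seed plus per-cell derived seeds
make results independent of evaluation order.

Distributions of mAUROC over grid cells are summarized by
`summarize_distribution()` (mean, min, p05, p50, p95, max, sd) and screened
by `predictability()`: a task is declared *not* predictable when its mAUROC
distribution is roughly symmetric with mean and median within 0.02 of 0.5
and |skewness| < 0.2, or when both its median and KDE-mode (Gaussian kernel,
Silverman bandwidth) fall below 0.5. These thresholds operationalize what
is otherwise a visual judgement, and are all exposed as arguments.

### Feature-length alignment

Trimming can leave different numbers of eigenvalues per scan while
classifiers need equal-length rows. `build_feature_table()` truncates every
feature vector to the dataset-wide minimum length, keeping the tail — for
ascending-sorted spectra this retains the largest, best-determined
eigenvalues, which also carry most group signal. This choice matters only
for the data-dependent trims (`largest`, `middle`).

## The synthetic generator

`synthesize_group_dataset()` emulates the aspects of multi-subject BOLD
data the pipeline depends on, without shipping any imaging data. Each scan
is a 3D grid (default 6 x 6 x 6 = 216 voxels) of t = 40 volumes: every
voxel is a random loading on `n_latent = 5` shared, temporally smoothed
latent signals of unit variance, plus iid Gaussian noise (sd 1). This
reproduces the structural facts that matter: t << N, spatially correlated
signal riding on noise, and exactly t - 1 nonzero correlation eigenvalues.
Group B's latent-signal strength is scaled by (1 + effect), so `effect = 0`
is an exchangeable null and larger values plant an increasing difference in
the correlation spectrum's shape. Four "preprocessing level" variants per
scan (increasing temporal smoothing plus low-frequency drift) exercise the
grid's preprocessing axis as labeled file variants, mirroring a design in
which preprocessing is an input label rather than a computation.

Defaults (20 scans per group, effect 2 for the planted case) were chosen
once as a small but realistic study size; with them the harness recovers
the planted effect with median mAUROC >= 0.9 over the raw-eigenvalue grid
and stays within [0.45, 0.55] mean mAUROC over 100 label permutations of a
null dataset, with mAUROC non-decreasing in effect size — all recomputed by
the test suite and the acceptance script.

What the generator does **not** emulate: hemodynamics, spatial
autocorrelation structure of real BOLD noise, motion artifacts, scanner
drift idiosyncrasies, subject-level repeated measures, or any anatomy.
Passing tests therefore demonstrate that the machinery is correct and
sensitive to planted spectral differences — not that eigenfeatures predict
any particular phenotype in real data.

## Problem sizes and numerical choices

The validation suites run at: Poisson n = 10000 (10 seeds), GOE n = 5000
(ensemble limits) and n = 2000 (Wigner spacings), exhaustive-oracle
comparisons at n <= 500, and end-to-end datasets of 40 scans x 4 levels.
These sizes were chosen as the smallest at which the closed-form limits are
comfortably resolved at the stated tolerances. Other numerical choices:
natural log for the eigenfeature transform (monotone, so
rank-based behavior is unaffected); linear interpolation (type-7) for all
percentiles; eigenvalues sorted ascending everywhere, with "first/last"
slice semantics defined against that order; clipping of non-positive values
to the precision threshold before logs, with a warning.

## Known limitations

* Fold assignment is a single stratified five-fold split per cell; repeated
  CV and subject-grouped folds (for multi-scan subjects) are not implemented
  — scans are treated as exchangeable samples.
* The logistic-regression classifier is deliberately absent, as are
  Gaussian unitary/symplectic ensembles, two-point cluster functions beyond
  Delta3/Sigma2, and exponential-family unfolding fits.
* Preprocessing of real fMRI (brain extraction, slice timing, motion
  correction, registration) is out of scope; preprocessing level is an
  input label on scans.
* `largest` trimming assumes the log-eigenvalue distribution separates into
  bulk and outliers; on unimodal spectra the 2-means split is arbitrary and
  the >50% guard is the only protection.
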