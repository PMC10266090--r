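# The multiverse harness: analytic grid, stratified five-fold cross-validated
# classification, metrics, and distribution summaries.

CLASSIFIER_IDS <- c("gbt", "rf", "svc_rbf", "knn3", "knn5", "knn9")

#' Enumerate the analytic grid
#'
#' Eigenfeatures are evaluated over 4 preprocessing levels x 2 normalization
#' methods x 4 trimming choices x 4 unfolding degrees x 10 slice choices
#' (1280 points). Baseline features over 4 preprocessing levels x 2
#' normalization methods x 5 smoothing windows (40 points). Enumeration is
#' deterministic, duplicate-free, and lexicographic over
#' (preprocessing, normalization, trim, degree, slice) resp.
#' (preprocessing, normalization, window).
#'
#' @param kind `"eigenfeature"` or `"baseline"`.
#' @return a data frame, one row per grid point.
#' @export
#' @examples
#' nrow(enumerate_grid("eigenfeature"))   # 1280
#' nrow(enumerate_grid("baseline"))       # 40
enumerate_grid <- function(kind = c("eigenfeature", "baseline")) {
  kind <- match.arg(kind)
  if (kind == "eigenfeature") {
    g <- expand.grid(
      slice = vapply(slice_specs(), format, ""),
      degree = c(3L, 5L, 7L, 9L),
      trim = c("none", "precision", "largest", "middle"),
      normalization = c("raw", "minmax"),
      preprocessing = 1:4,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("preprocessing", "normalization", "trim", "degree", "slice")]
  } else {
    g <- expand.grid(
      window = c(1L, 2L, 4L, 8L, 16L),
      normalization = c("raw", "minmax"),
      preprocessing = 1:4,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("preprocessing", "normalization", "window")]
  }
  rownames(g) <- NULL
  g
}

#' Total number of multiverse evaluations
#'
#' Grid accounting: `|eigenfeature grid| * 24 features * tasks * classifiers +
#' |baseline grid| * 10 features * tasks * classifiers`.
#'
#' @param n_tasks number of binary classification tasks (the full study has 11).
#' @param n_classifiers number of classifiers (default 6).
#' @return integer evaluation count.
#' @export
#' @examples
#' multiverse_total_evaluations(11)   # 2053920
multiverse_total_evaluations <- function(n_tasks = 11L, n_classifiers = 6L) {
  n_eig <- sum(feature_catalog()$coarse != "tseries")
  n_base <- sum(feature_catalog()$coarse == "tseries")
  (nrow(enumerate_grid("eigenfeature")) * n_eig +
     nrow(enumerate_grid("baseline")) * n_base) * n_tasks * n_classifiers
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank form: the probability a random positive scores above a
#' random negative, with ties counted half.
#'
#' @param scores continuous scores for the positive class.
#' @param labels binary labels (coercible to 0/1 factor).
#' @return AUROC in \[0, 1\]; 0.5 when one class is absent.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(0.5)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted accuracy
#'
#' Accuracy minus the proportion of the dataset's largest class, so positive
#' values mean better than majority-vote guessing.
#'
#' @param accuracy observed accuracy in \[0, 1\].
#' @param labels class labels of the entire dataset.
#' @return adjusted accuracy.
#' @export
#' @examples
#' adjusted_accuracy(0.8, rep(c(0, 1), c(60, 40)))   # 0.2
adjusted_accuracy <- function(accuracy, labels) {
  if (!length(labels)) stop("labels must be non-empty")
  accuracy - max(table(labels)) / length(labels)
}

f1_score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Fit `classifier_id` on (Xtr, ytr) and score Xte: returns list(score, pred)
# where score is the continuous positive-class score and pred the hard label.
# Positive class = second factor level. Library defaults throughout; gbt uses
# 100 boosting rounds.
fit_score <- function(classifier_id, Xtr, ytr, Xte) {
  ytr <- factor(ytr)
  pos <- levels(ytr)[2L]
  if (classifier_id %in% c("knn3", "knn5", "knn9")) {
    k <- as.integer(sub("knn", "", classifier_id))
    pr <- class::knn(Xtr, Xte, ytr, k = k, prob = TRUE)
    vote <- attr(pr, "prob")
    score <- ifelse(pr == pos, vote, 1 - vote)
    return(list(score = score, pred = as.character(pr)))
  }
  if (classifier_id == "svc_rbf") {
    fit <- e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE)
    pr <- predict(fit, Xte, probability = TRUE)
    score <- attr(pr, "probabilities")[, pos]
    return(list(score = score, pred = as.character(pr)))
  }
  if (classifier_id == "rf") {
    fit <- randomForest::randomForest(Xtr, ytr)
    score <- predict(fit, Xte, type = "prob")[, pos]
    pred <- as.character(predict(fit, Xte))
    return(list(score = score, pred = pred))
  }
  if (classifier_id == "gbt") {
    fit <- xgboost::xgboost(Xtr, ytr, nrounds = 100L, nthread = 1L,
                            verbosity = 0L)
    score <- predict(fit, Xte)   # probability of the second factor level
    return(list(score = score, pred = ifelse(score >= 0.5, pos, levels(ytr)[1L])))
  }
  stop("unknown classifier id: ", classifier_id)
}

# Stratified k-fold assignment; retries with successive seeds until every
# fold contains both classes (possible to fail only for tiny classes).
stratified_folds <- function(labels, k, seed) {
  y <- factor(labels)
  n <- length(y)
  for (try in 0:20) {
    folds <- integer(n)
    with_seed(seed + try, {
      for (lev in levels(y)) {
        idx <- which(y == lev)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[folds != f])) == 2L, TRUE))
    if (ok) {
      if (try > 0) message("re-split folds with seed offset ", try)
      return(folds)
    }
  }
  stop("could not build stratified folds with both classes in every training set")
}

#' Cross-validated evaluation of one feature matrix
#'
#' Stratified five-fold cross validation with a fixed split seed. Per fold the
#' classifier is fitted on the training rows and continuous positive-class
#' scores are computed on the validation rows, yielding AUROC, accuracy,
#' adjusted accuracy and F1. Min-max normalization statistics, when requested,
#' are fitted inside the training fold only. The natural-log transform for
#' eigenfeatures is applied up front (it has no fold-dependent statistics).
#' A constant feature matrix is flagged and scored at chance (mAUROC 0.5).
#'
#' @param features numeric matrix, samples x dimensions.
#' @param labels binary labels, one per row.
#' @param classifier_id one of `"gbt"`, `"rf"`, `"svc_rbf"`, `"knn3"`,
#'   `"knn5"`, `"knn9"`.
#' @param normalization `"raw"` or `"minmax"`.
#' @param is_eigenfeature apply the log transform before classification?
#' @param n_folds number of folds (default 5).
#' @param seed fold-split (and stochastic-classifier) seed.
#' @return a list of class `eval_result` with per-fold AUROCs, `mAUROC`, and
#'   mean `accuracy`, `adjusted_accuracy`, `f1`.
#' @export
crossval_evaluate <- function(features, labels, classifier_id = "knn5",
                              normalization = "raw", is_eigenfeature = TRUE,
                              n_folds = 5L, seed = 42L) {
  stopifnot(classifier_id %in% CLASSIFIER_IDS)
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must be binary")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  maj <- max(table(y)) / length(y)

  if (all(X == X[1L])) {
    warning("constant feature matrix: mAUROC defined as 0.5")
    return(structure(list(classifier_id = classifier_id,
                          fold_aurocs = rep(0.5, n_folds), mAUROC = 0.5,
                          accuracy = maj, adjusted_accuracy = 0,
                          f1 = NA_real_, degenerate = TRUE),
                     class = "eval_result"))
  }
  if (is_eigenfeature) {
    X <- normalize_features(X, method = "raw", is_eigenfeature = TRUE)$train
  }
  folds <- stratified_folds(y, n_folds, seed)
  met <- matrix(NA_real_, n_folds, 4L,
                dimnames = list(NULL, c("auroc", "acc", "adj", "f1")))
  pos <- levels(y)[2L]
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    nm <- normalize_features(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                             method = normalization, is_eigenfeature = FALSE)
    res <- with_seed(seed + 1000L * f,
                     fit_score(classifier_id, nm$train, y[tr], nm$test))
    truth <- as.character(y[te])
    met[f, "auroc"] <- auroc(res$score, y[te])
    met[f, "acc"] <- mean(res$pred == truth)
    met[f, "adj"] <- met[f, "acc"] - maj
    met[f, "f1"] <- f1_score(truth, res$pred, pos)
  }
  structure(list(classifier_id = classifier_id,
                 fold_aurocs = met[, "auroc"],
                 mAUROC = mean(met[, "auroc"]),
                 accuracy = mean(met[, "acc"]),
                 adjusted_accuracy = mean(met[, "adj"]),
                 f1 = mean(met[, "f1"]),
                 degenerate = FALSE),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mAUROC = %.3f (folds %s), acc = %.3f, adj = %+.3f, F1 = %.3f\n",
              x$classifier_id, x$mAUROC,
              paste(sprintf("%.2f", x$fold_aurocs), collapse = " "),
              x$accuracy, x$adjusted_accuracy, x$f1))
  invisible(x)
}

#' Seven-number summary of an mAUROC distribution
#'
#' Mean, min, 5th/50th/95th percentiles (linear interpolation), max and
#' standard deviation — the layout used for feature-level summaries.
#'
#' @param x numeric vector of mAUROCs (non-empty).
#' @return one-row data frame with columns `mean`, `min`, `p05`, `p50`,
#'   `p95`, `max`, `std`.
#' @export
summarize_distribution <- function(x) {
  if (!length(x)) stop("empty input")
  q <- stats::quantile(x, c(0.05, 0.50, 0.95), names = FALSE, type = 7)
  data.frame(mean = mean(x), min = min(x), p05 = q[1L], p50 = q[2L],
             p95 = q[3L], max = max(x), std = stats::sd(x))
}

#' Is a classification task predictable?
#'
#' Declares a task NOT predictable when its mAUROC distribution is (rule 1)
#' roughly symmetric with mean and median close to 0.5 — performance
#' indistinguishable from guessing — or (rule 2) has both median and mode
#' below 0.5. The mode is the argmax of a Gaussian kernel density estimate
#' with Silverman's rule-of-thumb bandwidth. All thresholds are exposed.
#'
#' @param mAUROCs numeric vector (>= 30 values required for a verdict).
#' @param mean_tol,median_tol closeness-to-0.5 tolerances for rule 1.
#' @param skew_tol absolute-skewness bound for "roughly symmetric".
#' @return list with `predictable` (logical, NA when too few values) and
#'   `reason` (character).
#' @export
predictability <- function(mAUROCs, mean_tol = 0.02, median_tol = 0.02,
                           skew_tol = 0.2) {
  if (length(mAUROCs) < 30L)
    return(list(predictable = NA, reason = "insufficient evidence (< 30 values)"))
  m <- mean(mAUROCs); md <- stats::median(mAUROCs)
  sk <- e1071::skewness(mAUROCs)
  if (is.na(sk)) sk <- 0
  if (abs(m - 0.5) < mean_tol && abs(md - 0.5) < median_tol && abs(sk) < skew_tol)
    return(list(predictable = FALSE,
                reason = "symmetric with mean and median close to 0.5"))
  d <- stats::density(mAUROCs, bw = "nrd0")
  mode <- d$x[which.max(d$y)]
  if (md < 0.5 && mode < 0.5)
    return(list(predictable = FALSE, reason = "median and mode below 0.5"))
  list(predictable = TRUE, reason = "distribution shifted above chance")
}

#' Build a per-scan feature table
#'
#' Computes one catalog feature for every scan of a dataset and stacks the
#' vectors into a samples x dimensions matrix. Trimming can leave different
#' numbers of eigenvalues per scan; vectors are aligned by truncating to the
#' dataset-wide minimum length keeping the tail (for ascending-sorted spectra
#' this keeps the largest, best-determined values).
#'
#' @param scans list of N x t matrices (one per scan).
#' @param id feature identifier.
#' @param ... passed to [compute_feature()].
#' @return numeric matrix with `length(scans)` rows.
#' @export
build_feature_table <- function(scans, id, ...) {
  vecs <- lapply(scans, compute_feature, id = id, ...)
  p <- min(lengths(vecs))
  do.call(rbind, lapply(vecs, function(v) utils::tail(as.numeric(v), p)))
}

#' Evaluate one feature over a grid of analytic choices
#'
#' Runs [crossval_evaluate()] for every combination of grid row and
#' classifier on a dataset held in memory as per-preprocessing-level scan
#' matrices. This is the multiverse inner loop at dataset scale; cells are
#' independent and seeded per-cell from `seed` so results do not depend on
#' evaluation order.
#'
#' @param dataset a list with elements `scans` (list over preprocessing
#'   levels, each a list of N x t matrices) and `labels` (one per scan).
#' @param feature_id catalog feature identifier.
#' @param grid data frame as from [enumerate_grid()] (or a subset of rows).
#' @param classifiers character vector of classifier ids.
#' @param seed root seed.
#' @return data frame: one row per (grid row x classifier) with the grid
#'   columns, `classifier`, `mAUROC`, `accuracy`, `adjusted_accuracy`, `f1`.
#' @export
evaluate_feature_grid <- function(dataset, feature_id, grid,
                                  classifiers = "knn5", seed = 42L) {
  is_eig <- !startsWith(feature_id, "T-")
  out <- vector("list", nrow(grid) * length(classifiers))
  row_i <- 0L
  feat_cache <- new.env(parent = emptyenv())
  for (g in seq_len(nrow(grid))) {
    gp <- grid[g, , drop = FALSE]
    lev <- gp$preprocessing
    key <- paste(feature_id, lev,
                 if (is_eig) paste(gp$trim, gp$degree, gp$slice) else gp$window)
    if (is.null(feat_cache[[key]])) {
      feat_cache[[key]] <- if (is_eig) {
        sl_parts <- strsplit(gp$slice, "-", fixed = TRUE)[[1L]]
        sl <- if (sl_parts[1L] == "full") slice_spec("full")
              else slice_spec(sl_parts[1L], as.numeric(sl_parts[2L]))
        build_feature_table(dataset$scans[[lev]], feature_id,
                            trim = gp$trim, degree = gp$degree, slice = sl,
                            seed = seed)
      } else {
        build_feature_table(dataset$scans[[lev]], feature_id, window = gp$window)
      }
    }
    X <- feat_cache[[key]]
    for (cl in classifiers) {
      row_i <- row_i + 1L
      ev <- crossval_evaluate(X, dataset$labels, classifier_id = cl,
                              normalization = gp$normalization,
                              is_eigenfeature = is_eig,
                              seed = seed + 7L * g)
      out[[row_i]] <- cbind(gp,
                            data.frame(classifier = cl, mAUROC = ev$mAUROC,
                                       accuracy = ev$accuracy,
                                       adjusted_accuracy = ev$adjusted_accuracy,
                                       f1 = ev$f1, stringsAsFactors = FALSE),
                            row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  res$feature_id <- feature_id
  rownames(res) <- NULL
  res
}
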