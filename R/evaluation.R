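#' Stratified k-fold assignment
#'
#' Splits indices into k folds preserving per-class proportions: within
#' each class the points are shuffled (seeded) and dealt round-robin, so
#' per-class fold counts differ by at most one.
#'
#' @param labels Vector of class labels (any type coercible to factor).
#' @param k Number of folds (>= 2); every class must have >= k members.
#' @param seed Integer seed.
#' @return Object of class `"fold_assignment"`: list with `k`, `fold`
#'   (integer in 1..k per point), `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  f <- factor(labels)
  counts <- table(f)
  small <- counts < k
  if (any(small))
    stopf("stratification error: class '%s' has %d point(s) but k = %d",
          names(counts)[small][1L], counts[small][1L], k)
  fold <- integer(length(f))
  with_seed(seed, {
    for (cl in levels(f)) {
      idx <- which(f == cl)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Multiclass confusion matrix (predicted x actual)
#'
#' Counts are laid out with rows = predicted class and columns = actual
#' class, so column sums are the per-class actual totals.
#'
#' @param predicted,actual Label vectors of equal length.
#' @param classes Class order; defaults to the union of levels.
#' @return Integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(predicted, actual, classes = NULL) {
  if (length(predicted) != length(actual))
    stopf("predicted and actual differ in length")
  if (is.null(classes))
    classes <- union(levels(factor(actual)), levels(factor(predicted)))
  p <- factor(predicted, levels = classes)
  a <- factor(actual, levels = classes)
  if (anyNA(p) || anyNA(a))
    stopf("labels outside the declared class set")
  m <- table(predicted = p, actual = a)
  structure(unclass(m), class = "confusion_matrix")
}

#' Overall classification accuracy
#'
#' The ratio of correct classifications (the diagonal) over all evaluated
#' points.
#'
#' @param cm A `"confusion_matrix"` (or any predicted x actual matrix).
#' @return Scalar in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (!total) stopf("empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' Column-normalized confusion-ratio matrix
#'
#' Divides each column of the confusion matrix by its actual-class total.
#' Diagonals are per-class recall; off-diagonals are misclassification
#' rates. Columns sum to one exactly (before any display rounding).
#'
#' @param cm A `"confusion_matrix"`.
#' @return Matrix of class `"confusion_ratio_matrix"` with entries in
#'   \[0, 1\].
#' @export
column_normalize <- function(cm) {
  m <- as.matrix(cm)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero))
    stopf("normalization error: actual class '%s' has no points",
          colnames(m)[zero][1L])
  structure(sweep(m, 2L, tot, "/"), class = "confusion_ratio_matrix")
}

#' @export
print.confusion_ratio_matrix <- function(x, digits = 3L, ...) {
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Sensitivity and specificity of a two-class confusion matrix
#'
#' With rows = predicted and columns = actual, and the first class taken as
#' positive: sensitivity = TP / (TP + FN) (true-positive rate) and
#' specificity = TN / (TN + FP) (true-negative rate).
#'
#' @param cm2 A 2 x 2 predicted x actual count matrix.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(cm2) {
  m <- as.matrix(cm2)
  if (!all(dim(m) == 2L)) stopf("need a 2 x 2 confusion matrix")
  tp <- m[1L, 1L]; fn <- m[2L, 1L]; fp <- m[1L, 2L]; tn <- m[2L, 2L]
  if (tp + fn == 0) stopf("sensitivity undefined: no actual positives")
  if (tn + fp == 0) stopf("specificity undefined: no actual negatives")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Collapse a multiclass confusion matrix to one-vs-rest
#'
#' @param cm An R x R `"confusion_matrix"`.
#' @param positive The class treated as positive (first row/column of the
#'   returned 2 x 2 matrix).
#' @return A 2 x 2 `"confusion_matrix"` with classes
#'   `c(positive, "rest")`.
#' @export
binary_collapse <- function(cm, positive) {
  m <- as.matrix(cm)
  if (!positive %in% rownames(m)) stopf("unknown class '%s'", positive)
  p <- rownames(m) == positive
  out <- rbind(c(m[p, p], sum(m[p, !p])),
               c(sum(m[!p, p]), sum(m[!p, !p])))
  dimnames(out) <- list(predicted = c(positive, "rest"),
                        actual = c(positive, "rest"))
  structure(out, class = "confusion_matrix")
}

#' Cobweb (radar) coordinates of the misclassification rates
#'
#' Enumerates the R^2 - R off-diagonal entries of a confusion-ratio matrix
#' column-major: for each actual class in order, the rates of being
#' predicted as each other class. A chance classifier puts 1/R on every
#' axis; any classifier whose polygon lies inside the chance polygon beats
#' chance on every error type.
#'
#' @param crm A `"confusion_ratio_matrix"`.
#' @return Object of class `"cobweb_polygon"`: data frame with columns
#'   `axis` (label "as <predicted> | actual <actual>"), `predicted`,
#'   `actual`, `value`, plus attribute `chance` = 1/R.
#' @export
cobweb_coordinates <- function(crm) {
  m <- as.matrix(crm)
  classes <- colnames(m)
  r <- length(classes)
  rows <- do.call(rbind, lapply(classes, function(a) {
    others <- setdiff(classes, a)
    data.frame(predicted = others, actual = a,
               value = m[others, a], stringsAsFactors = FALSE)
  }))
  rows$axis <- sprintf("as %s | actual %s", rows$predicted, rows$actual)
  rownames(rows) <- NULL
  structure(rows[, c("axis", "predicted", "actual", "value")],
            chance = 1 / r, class = c("cobweb_polygon", "data.frame"))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold, trains a fresh classifier on the other k - 1 folds and
#' evaluates on the held-out fold; all held-out predictions are pooled into
#' one confusion matrix. The headline metric is the mean of the k fold
#' accuracies; the pooled-matrix accuracy is reported alongside (the two
#' differ slightly when folds are unequal).
#'
#' @param x Feature matrix or data frame.
#' @param y Class labels.
#' @param k Number of folds (default 10).
#' @param seed Master seed: expanded into sub-seeds for the fold split and
#'   each fold's training, so one integer reproduces the whole run.
#' @param trainer `function(x, y, seed) -> model` used per fold; defaults
#'   to [fit_bdt()] with `plan` and `config` (the seed re-seeds the PSO).
#' @param predictor `function(model, x) -> labels`.
#' @param plan,config Passed to the default trainer; see [fit_bdt()].
#' @param ... Further arguments to the default trainer ([fit_bdt()]).
#' @return Object of class `"cv_result"`: `fold_accuracy` (length k),
#'   `mean_accuracy`, `pooled_accuracy`, `confusion` (pooled
#'   `"confusion_matrix"`), `folds`, and per-fold `node_hyper` records for
#'   the default trainer.
#' @export
cross_validate <- function(x, y, k = 10L, seed = 1L,
                           trainer = NULL, predictor = predict,
                           plan = NULL, config = swarm_config(), ...) {
  x <- as_feature_matrix(x)
  y <- factor(y)
  classes <- levels(y)
  default_trainer <- is.null(trainer)
  if (default_trainer)
    trainer <- function(x, y, seed) {
      cfg <- config
      cfg$seed <- seed
      fit_bdt(x, y, plan = plan, config = cfg, ...)
    }
  assign <- stratified_kfold(y, k, derive_seed(seed, 1L))
  fold_acc <- numeric(k)
  pred_all <- character(length(y))
  node_hyper <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- assign$fold != f
    model <- trainer(x[tr, , drop = FALSE], as.character(y)[tr],
                     derive_seed(seed, 1000L + f))
    p <- as.character(predictor(model, x[!tr, , drop = FALSE]))
    pred_all[!tr] <- p
    fold_acc[f] <- mean(p == as.character(y)[!tr])
    if (default_trainer && inherits(model, "bdt"))
      node_hyper[[f]] <- lapply(model$node_tuning, function(t)
        t[c("log2_gamma", "log2_sigma2", "inner_cv_accuracy")])
  }
  cm <- confusion_matrix(pred_all, as.character(y), classes)
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = overall_accuracy(cm),
                 confusion = cm, folds = assign,
                 node_hyper = node_hyper, k = k, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV: mean accuracy %.4f (pooled %.4f)\n",
              x$k, x$mean_accuracy, x$pooled_accuracy))
  cat("fold accuracies:",
      paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}
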