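#' Binary class-partition plan
#'
#' A binary decision tree over R classes is described by an ordered list of
#' R - 1 splits. Each split names its parent class set and the positive and
#' negative subsets (disjoint, non-empty, union = parent). The first split's
#' parent is the full class set; every later parent must be a subset
#' produced by an earlier split; leaves are exactly the R singletons.
#'
#' @param classes Ordered character vector of R >= 2 class names.
#' @param splits List of splits, each a list with elements `parent`,
#'   `positive`, `negative` (character vectors). The positive subset maps
#'   to +1 at that node's LS-SVM.
#' @return Object of class `"partition_plan"`.
#' @seealso [ctg_plan()] for the fixed fetal-state tree.
#' @export
partition_plan <- function(classes, splits) {
  classes <- as.character(classes)
  r <- length(classes)
  if (r < 2L) stopf("need at least 2 classes")
  if (anyDuplicated(classes)) stopf("duplicate class names")
  if (length(splits) != r - 1L)
    stopf("plan must have exactly R - 1 = %d splits, got %d",
          r - 1L, length(splits))

  pending <- list(classes) # non-singleton subsets awaiting a split
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    for (f in c("parent", "positive", "negative"))
      if (is.null(s[[f]])) stopf("split %d lacks '%s'", i, f)
    par <- as.character(s$parent)
    pos <- as.character(s$positive)
    neg <- as.character(s$negative)
    if (!length(pos) || !length(neg))
      stopf("split %d: positive and negative subsets must be non-empty", i)
    if (length(intersect(pos, neg)))
      stopf("split %d: overlapping positive/negative subsets (%s)",
            i, paste(intersect(pos, neg), collapse = ", "))
    if (!setequal(union(pos, neg), par))
      stopf("split %d: positive + negative must partition the parent set", i)
    hit <- which(vapply(pending, setequal, logical(1), y = par))
    if (!length(hit))
      stopf("split %d: parent {%s} is not an unsplit internal node",
            i, paste(par, collapse = ", "))
    pending <- pending[-hit[1L]]
    for (sub in list(pos, neg))
      if (length(sub) > 1L) pending <- c(pending, list(sub))
    splits[[i]] <- list(parent = par, positive = pos, negative = neg)
  }
  if (length(pending))
    stopf("plan leaves internal node(s) unsplit: {%s}",
          paste(vapply(pending, paste, "", collapse = ", "), collapse = "}, {"))
  structure(list(classes = classes, splits = splits),
            class = "partition_plan")
}

#' The fixed fetal-state decision tree
#'
#' Root: \{pathologic, suspect\} (positive) versus \{normal\}; second node:
#' pathologic (positive) versus suspect. Grouping the two at-risk states
#' together at the root minimizes the risk of routing an abnormal fetus
#' down the normal branch on a single mistake.
#'
#' @return A `"partition_plan"` over [ctg_classes] with exactly 2 splits.
#' @export
ctg_plan <- function() {
  partition_plan(ctg_classes, list(
    list(parent = ctg_classes,
         positive = c("pathologic", "suspect"), negative = "normal"),
    list(parent = c("pathologic", "suspect"),
         positive = "pathologic", negative = "suspect")))
}

# Stratified CV accuracy of the LS-SVM at (gamma, sigma2) on one node's
# binary problem, with per-fold distance matrices precomputed so each
# hyperparameter evaluation only pays exp() + one Cholesky solve per fold.
make_node_fitness <- function(x, yy, inner_folds, seed, scale) {
  counts <- table(yy)
  k <- as.integer(min(inner_folds, floor(min(counts) / 2)))
  if (k < 2L) {
    warning("too few minority points for inner CV; using training accuracy",
            call. = FALSE)
    prep <- local({
      sc <- if (scale) standardize_fit(x) else NULL
      xs <- if (scale) standardize_apply(sc, x) else x
      list(list(d_tr = row_sqdist(xs), y_tr = yy,
                d_val = row_sqdist(xs), y_val = yy))
    })
  } else {
    fold <- stratified_kfold(yy, k, seed)$fold
    prep <- lapply(seq_len(k), function(f) {
      tr <- fold != f
      sc <- if (scale) standardize_fit(x[tr, , drop = FALSE]) else NULL
      xs_tr <- if (scale) standardize_apply(sc, x[tr, , drop = FALSE]) else
        x[tr, , drop = FALSE]
      xs_va <- if (scale) standardize_apply(sc, x[!tr, , drop = FALSE]) else
        x[!tr, , drop = FALSE]
      list(d_tr = row_sqdist(xs_tr), y_tr = yy[tr],
           d_val = row_sqdist(xs_va, xs_tr), y_val = yy[!tr])
    })
  }
  list(
    inner_folds = if (k < 2L) 0L else k,
    fitness = function(pos) {
      gamma <- 2^pos[1L]
      sigma2 <- 2^pos[2L]
      accs <- vapply(prep, function(p) {
        sol <- lssvm_solve_kernel(exp(-p$d_tr / (2 * sigma2)), p$y_tr, gamma)
        f <- drop(exp(-p$d_val / (2 * sigma2)) %*% (p$y_tr * sol$alpha)) +
          sol$b
        mean(ifelse(f >= 0, 1, -1) == p$y_val)
      }, numeric(1))
      mean(accs)
    })
}

# On equal fitness prefer the smaller gamma (first log2 coordinate).
prefer_smaller_gamma <- function(candidate, incumbent) {
  candidate[1L] < incumbent[1L]
}

#' Fit a multiclass LS-SVM binary decision tree
#'
#' Trains one binary LS-SVM per split of `plan` (R - 1 in total), each on
#' only the rows whose class belongs to that split's parent set, with the
#' positive subset recoded to +1. By default each node's penalty factor
#' gamma and kernel width sigma2 are tuned by particle swarm optimization
#' in log2 space, maximizing the mean accuracy of an internal stratified
#' cross-validation on that node's training rows (folds reduced
#' automatically, with a warning, when the minority class is too small for
#' `inner_folds`).
#'
#' @param x Feature matrix or data frame (rows = points).
#' @param y Class labels (factor or character) drawn from `plan$classes`;
#'   every class in the plan needs >= 2 rows.
#' @param plan A [partition_plan()]; defaults to the fetal-state tree when
#'   the labels are exactly [ctg_classes].
#' @param config A [swarm_config()] governing every node's PSO (each node
#'   derives its own sub-seed, so nodes explore independently).
#' @param tune If `FALSE`, skip PSO and use `gamma`/`sigma2` directly.
#' @param gamma,sigma2 Fixed hyperparameters when `tune = FALSE`; scalars
#'   (recycled) or vectors of length R - 1.
#' @param scale Standardize features per node (see [lssvm()]).
#' @param inner_folds Target number of inner CV folds for the PSO fitness.
#' @return Object of class `"bdt"`: the plan, one `"lssvm"` per split, and
#'   per-node tuning records (chosen log2 position, fitness, history).
#' @examples
#' d <- generate_ctg(n_per_class = c(60, 20, 15), seed = 3)
#' tr <- fit_bdt(d[, 1:21], d$state, tune = FALSE, gamma = 10, sigma2 = 21)
#' table(predicted = predict(tr, d[, 1:21]), actual = d$state)
#' @export
fit_bdt <- function(x, y, plan = NULL, config = swarm_config(),
                    tune = TRUE, gamma = NULL, sigma2 = NULL,
                    scale = TRUE, inner_folds = 5L) {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  if (is.null(plan)) {
    if (!setequal(unique(y), ctg_classes))
      stopf("no plan given and labels are not the three fetal states")
    plan <- ctg_plan()
  }
  stopifnot(inherits(plan, "partition_plan"))
  counts <- table(factor(y, levels = plan$classes))
  if (any(counts < 2L))
    stopf("degenerate input: class '%s' has %d point(s), need >= 2",
          names(counts)[which.min(counts)], min(counts))
  n_nodes <- length(plan$splits)
  if (!tune) {
    if (is.null(gamma) || is.null(sigma2))
      stopf("tune = FALSE requires gamma and sigma2")
    gamma <- rep_len(gamma, n_nodes)
    sigma2 <- rep_len(sigma2, n_nodes)
  }

  models <- vector("list", n_nodes)
  tuning <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    s <- plan$splits[[i]]
    idx <- y %in% s$parent
    xi <- x[idx, , drop = FALSE]
    yy <- ifelse(y[idx] %in% s$positive, 1, -1)
    if (tune) {
      node_cfg <- config
      node_cfg$seed <- derive_seed(config$seed, i)
      nf <- make_node_fitness(xi, yy, inner_folds,
                              seed = derive_seed(node_cfg$seed, 101L),
                              scale = scale)
      opt <- pso_optimize(nf$fitness, node_cfg,
                          tie_breaker = prefer_smaller_gamma)
      g <- 2^opt$position[1L]
      s2 <- 2^opt$position[2L]
      tuning[[i]] <- list(log2_gamma = opt$position[1L],
                          log2_sigma2 = opt$position[2L],
                          inner_cv_accuracy = opt$fitness,
                          inner_folds = nf$inner_folds,
                          history = opt$history)
    } else {
      g <- gamma[i]
      s2 <- sigma2[i]
      tuning[[i]] <- list(log2_gamma = log2(g), log2_sigma2 = log2(s2),
                          inner_cv_accuracy = NA_real_, inner_folds = 0L,
                          history = numeric(0))
    }
    models[[i]] <- lssvm(xi, yy, gamma = g, sigma2 = s2, scale = scale)
  }
  structure(list(plan = plan, node_models = models, node_tuning = tuning,
                 classes = plan$classes, format_version = 1L),
            class = "bdt")
}

#' Predict classes from a fitted decision tree
#'
#' Each point is routed from the root: the node model's binary prediction
#' selects the positive or negative child subset, recursing until a single
#' class remains.
#'
#' @param object A fitted `"bdt"`.
#' @param newdata Feature matrix (or single-point vector).
#' @param ... Unused.
#' @return Factor of predicted classes with levels `object$classes`.
#' @export
predict.bdt <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  n <- nrow(newdata)
  out <- character(n)
  route <- function(class_set, rows) {
    if (!length(rows)) return()
    if (length(class_set) == 1L) {
      out[rows] <<- class_set
      return()
    }
    i <- which(vapply(object$plan$splits, function(s)
      setequal(s$parent, class_set), logical(1)))[1L]
    s <- object$plan$splits[[i]]
    pred <- predict(object$node_models[[i]],
                    newdata[rows, , drop = FALSE])
    route(s$positive, rows[pred > 0])
    route(s$negative, rows[pred < 0])
  }
  route(object$classes, seq_len(n))
  factor(out, levels = object$classes)
}

#' @export
print.bdt <- function(x, ...) {
  cat(sprintf("LS-SVM binary decision tree: %d classes, %d node model(s)\n",
              length(x$classes), length(x$node_models)))
  for (i in seq_along(x$plan$splits)) {
    s <- x$plan$splits[[i]]
    t <- x$node_tuning[[i]]
    cat(sprintf("  node %d: {%s} vs {%s}  gamma = %.4g, sigma2 = %.4g%s\n",
                i, paste(s$positive, collapse = ","),
                paste(s$negative, collapse = ","),
                2^t$log2_gamma, 2^t$log2_sigma2,
                if (is.na(t$inner_cv_accuracy)) "" else
                  sprintf(" (inner CV acc %.3f)", t$inner_cv_accuracy)))
  }
  invisible(x)
}

#' Serialize / restore a decision tree as JSON
#'
#' One JSON document embeds the partition plan, every node model, and the
#' per-node tuning traces.
#'
#' @param object A fitted `"bdt"`.
#' @param path File path.
#' @return `write_bdt` returns `path` invisibly; `read_bdt` the restored
#'   `"bdt"`.
#' @export
write_bdt <- function(object, path) {
  stopifnot(inherits(object, "bdt"))
  doc <- list(type = "bdt", format_version = object$format_version,
              classes = object$classes,
              splits = object$plan$splits,
              node_models = lapply(object$node_models, lssvm_to_list),
              node_tuning = object$node_tuning)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bdt
#' @export
read_bdt <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$type) || doc$type != "bdt")
    stopf("not a bdt JSON document")
  splits <- lapply(seq_len(nrow_or_len(doc$splits)), function(i)
    lapply(pick_row(doc$splits, i), as.character))
  plan <- partition_plan(as.character(doc$classes), splits)
  models <- lapply(seq_along(doc$node_models), function(i)
    lssvm_from_list(pick_row(doc$node_models, i)))
  structure(list(plan = plan, node_models = models,
                 node_tuning = doc$node_tuning,
                 classes = plan$classes,
                 format_version = doc$format_version),
            class = "bdt")
}

# jsonlite may simplify a homogeneous list of records into a data frame;
# these helpers iterate either representation uniformly.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) col[[i]] else col[i])
  else x[[i]]
}
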