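#' Build the LS-SVM Karush-Kuhn-Tucker linear system
#'
#' Training a least-squares SVM amounts to solving one linear system in the
#' bias `b` and the Lagrange multipliers `alpha`. With
#' \eqn{\Omega_{ij} = y_i y_j K(x_i, x_j)} the system is the bordered
#' \eqn{(N+1)\times(N+1)} block matrix
#' \deqn{\left[\begin{array}{cc} 0 & -Y^\top \\ Y & \Omega + \gamma^{-1} I
#' \end{array}\right] \left[\begin{array}{c} b \\ \alpha \end{array}\right]
#' = \left[\begin{array}{c} 0 \\ 1 \end{array}\right].}
#' The first row encodes the optimality condition \eqn{\sum_i \alpha_i y_i
#' = 0}. `form = "symmetric"` flips the sign of the first row (same
#' solution set, symmetric matrix).
#'
#' @param x N x p numeric feature matrix (rows are points).
#' @param y Numeric label vector in {-1, +1}; both labels must occur.
#' @param gamma Positive penalty factor \eqn{\gamma} on squared residuals.
#' @param sigma2 Positive RBF kernel width \eqn{\sigma^2}.
#' @param form `"paper"` for the bordered system with `-Y^T` in the first
#'   row, `"symmetric"` for the sign-flipped symmetric variant.
#' @return An object of class `"kkt_system"`: list with `matrix`
#'   ((N+1) x (N+1)), `rhs` (c(0, 1, ..., 1)), `omega`, `y`.
#' @seealso [lssvm()]
#' @export
build_kkt_system <- function(x, y, gamma, sigma2,
                             form = c("paper", "symmetric")) {
  form <- match.arg(form)
  x <- as_feature_matrix(x)
  check_finite(x, "x")
  y <- check_pm1_labels(y)
  n <- nrow(x)
  if (n < 2L) stopf("need at least 2 training points, got %d", n)
  if (length(y) != n) stopf("length(y) = %d but nrow(x) = %d", length(y), n)
  check_hyper(gamma, sigma2)

  kmat <- rbf_kernel_matrix(x, sigma2 = sigma2)
  omega <- tcrossprod(y) * kmat
  a <- omega + diag(1 / gamma, n)
  sgn <- if (form == "paper") -1 else 1
  m <- unname(rbind(c(0, sgn * y), cbind(y, a)))
  structure(list(matrix = m, rhs = c(0, rep(1, n)), omega = omega, y = y,
                 gamma = gamma, sigma2 = sigma2, form = form),
            class = "kkt_system")
}

check_pm1_labels <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stopf("labels must be coded -1/+1")
  if (length(unique(y)) < 2L)
    stopf("degenerate input: only one class present in y")
  y
}

check_hyper <- function(gamma, sigma2) {
  for (nm in c("gamma", "sigma2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("%s must be a positive finite scalar (got %s)", nm, format(v))
  }
  invisible(NULL)
}

# Core solve given a precomputed kernel matrix; used both by lssvm() and by
# the PSO tuning inner loop, where the squared-distance matrix is cached and
# only exp()+solve are paid per hyperparameter evaluation.
#
# Block elimination with A = Omega + I/gamma (symmetric positive definite):
#   b = (y' A^-1 1) / (y' A^-1 y),  alpha = A^-1 (1 - b y).
# This is the exact solution of the printed bordered system (the sign of its
# first row is irrelevant since that row's right-hand side is 0).
lssvm_solve_kernel <- function(kmat, y, gamma) {
  n <- length(y)
  a <- tcrossprod(y) * kmat
  diag(a) <- diag(a) + 1 / gamma
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch))
    stopf("KKT system numerically singular or indefinite at gamma=%g", gamma)
  rhs <- cbind(rep(1, n), y)
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  v <- sol[, 1L] # A^-1 1
  u <- sol[, 2L] # A^-1 y
  den <- sum(y * u)
  if (!is.finite(den) || abs(den) < .Machine$double.eps * n)
    stopf("KKT system degenerate: y' A^-1 y ~ 0 at gamma=%g", gamma)
  b <- sum(y * v) / den
  list(alpha = v - b * u, b = b)
}

#' Fit a binary least-squares support vector machine
#'
#' Solves the LS-SVM optimality (KKT) system for the Gaussian-kernel
#' classifier \eqn{f(x) = \mathrm{sign}(\sum_i y_i \alpha_i K(x, x_i) + b)}.
#' Unlike the classical SVM there is no quadratic program: the equality
#' constraints and squared loss reduce training to one dense linear solve,
#' and every training point carries a (possibly negative) multiplier.
#'
#' Features are z-score standardized by default (`scale = TRUE`); the RBF
#' kernel is scale-sensitive and the CTG features live on very different
#' scales. The standardization is fit on the training data, stored in the
#' model, and applied to queries.
#'
#' @inheritParams build_kkt_system
#' @param scale Standardize features to zero mean / unit variance before
#'   computing kernel distances (recommended; disable for strict raw-feature
#'   behaviour).
#' @param solver `"chol"` (default) solves via block elimination with a
#'   Cholesky factorization of \eqn{\Omega + \gamma^{-1} I}; `"lu"` does a
#'   dense partial-pivoting solve of the literal (N+1) x (N+1) bordered
#'   matrix. Both return the same solution to solver tolerance.
#' @param form Sign convention of the bordered system (see
#'   [build_kkt_system()]); only consulted when `solver = "lu"`.
#' @return Object of class `"lssvm"`: training points (as standardized),
#'   labels, `alpha`, `b`, hyperparameters, the scaling record, and the
#'   relative residual of the printed KKT system at the solution.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c(1, -1), each = 20)
#' m <- lssvm(x, y, gamma = 10, sigma2 = 2)
#' mean(predict(m, x) == y)
#' @export
lssvm <- function(x, y, gamma, sigma2, scale = TRUE,
                  solver = c("chol", "lu"), form = c("paper", "symmetric")) {
  solver <- match.arg(solver)
  form <- match.arg(form)
  x <- as_feature_matrix(x)
  check_finite(x, "x")
  y <- check_pm1_labels(y)
  if (length(y) != nrow(x))
    stopf("length(y) = %d but nrow(x) = %d", length(y), nrow(x))
  check_hyper(gamma, sigma2)

  scaling <- if (scale) standardize_fit(x) else NULL
  xs <- if (scale) standardize_apply(scaling, x) else x

  kmat <- rbf_kernel_matrix(xs, sigma2 = sigma2)
  if (solver == "chol") {
    sol <- tryCatch(lssvm_solve_kernel(kmat, y, gamma), error = function(e)
      stopf("LS-SVM solve failed at gamma=%g, sigma2=%g: %s",
            gamma, sigma2, conditionMessage(e)))
    alpha <- sol$alpha
    b <- sol$b
  } else {
    sys <- build_kkt_system(xs, y, gamma, sigma2, form = form)
    sol <- tryCatch(solve(sys$matrix, sys$rhs), error = function(e)
      stopf("KKT system numerically singular at gamma=%g, sigma2=%g: %s",
            gamma, sigma2, conditionMessage(e)))
    b <- sol[1L]
    alpha <- sol[-1L]
  }
  alpha <- unname(alpha)
  b <- unname(b)

  # Relative residual of the literal printed system (diagnostic).
  omega <- tcrossprod(y) * kmat
  n <- length(y)
  r1 <- -sum(y * alpha)
  r2 <- y * b + (omega + diag(1 / gamma, n)) %*% alpha - 1
  resid <- sqrt(r1^2 + sum(r2^2)) / sqrt(n)

  structure(list(train_points = xs, train_labels = y, alpha = alpha, b = b,
                 gamma = gamma, sigma2 = sigma2, scaling = scaling,
                 solver = solver, kkt_residual = resid,
                 format_version = 1L),
            class = "lssvm")
}

#' LS-SVM decision values
#'
#' The real-valued quantity inside the sign of the classifier,
#' \eqn{\sum_i y_i \alpha_i K(x, x_i) + b}. Its sign is the predicted label;
#' its magnitude grows with distance from the decision boundary.
#'
#' @param object A fitted `"lssvm"` model.
#' @param newdata Matrix (or vector for a single point) with the model's
#'   feature dimension.
#' @return Numeric vector of decision values, one per row of `newdata`.
#' @export
decision_values <- function(object, newdata) UseMethod("decision_values")

#' @export
decision_values.lssvm <- function(object, newdata) {
  p <- ncol(object$train_points)
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != p)
    stopf("dimension mismatch: model has %d features, newdata has %d",
          p, ncol(newdata))
  if (!is.null(object$scaling))
    newdata <- standardize_apply(object$scaling, newdata)
  kmat <- rbf_kernel_matrix(newdata, object$train_points, object$sigma2)
  drop(kmat %*% (object$train_labels * object$alpha)) + object$b
}

#' Predict class labels from a binary LS-SVM
#'
#' @param object A fitted `"lssvm"` model.
#' @param newdata Feature matrix or single-point vector.
#' @param ... Unused.
#' @return Vector of labels in {-1, +1}. A decision value of exactly 0 maps
#'   to +1 (deterministic `sign(0) >= 0` convention).
#' @export
predict.lssvm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  ifelse(f >= 0, 1, -1)
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "LS-SVM (RBF): N = %d, p = %d, gamma = %g, sigma2 = %g, b = %.4g\n",
    length(x$train_labels), ncol(x$train_points), x$gamma, x$sigma2, x$b))
  cat(sprintf("KKT residual (rel.): %.3g; scaling: %s\n",
              x$kkt_residual, if (is.null(x$scaling)) "off" else "z-score"))
  invisible(x)
}

#' Serialize / restore an LS-SVM model as JSON
#'
#' Writes a single self-describing JSON document (training points, labels,
#' multipliers, bias, hyperparameters, scaling record, format version).
#'
#' @param object A fitted `"lssvm"`.
#' @param path File path to write to / read from.
#' @return `write_lssvm` returns `path` invisibly; `read_lssvm` returns the
#'   restored `"lssvm"` object.
#' @export
write_lssvm <- function(object, path) {
  stopifnot(inherits(object, "lssvm"))
  jsonlite::write_json(lssvm_to_list(object), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

lssvm_to_list <- function(object) {
  list(type = "lssvm", format_version = object$format_version,
       train_points = unclass(object$train_points),
       train_labels = object$train_labels,
       alpha = object$alpha, b = object$b,
       gamma = object$gamma, sigma2 = object$sigma2,
       scaling = if (is.null(object$scaling)) NULL else
         list(center = object$scaling$center, scale = object$scaling$scale))
}

#' @rdname write_lssvm
#' @export
read_lssvm <- function(path) {
  lssvm_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

lssvm_from_list <- function(doc) {
  if (is.null(doc$type) || doc$type != "lssvm")
    stopf("not an lssvm JSON document")
  scaling <- if (!is.null(doc$scaling))
    structure(list(center = as.numeric(doc$scaling$center),
                   scale = as.numeric(doc$scaling$scale)),
              class = "standardizer")
  structure(list(train_points = as.matrix(doc$train_points),
                 train_labels = as.numeric(doc$train_labels),
                 alpha = as.numeric(doc$alpha), b = as.numeric(doc$b),
                 gamma = doc$gamma, sigma2 = doc$sigma2,
                 scaling = scaling, solver = "chol",
                 kkt_residual = NA_real_,
                 format_version = doc$format_version),
            class = "lssvm")
}
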