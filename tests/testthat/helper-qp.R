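# Independent QP oracle: classical soft-margin SVM dual solved by
# simplified SMO (sequential minimal optimization). Used to check that the
# LS-SVM linear-system solution approaches the hard-margin SVM as the
# penalty factor grows. Shares no code with the package's solve path (the
# kernel here goes through stats::dist).

smo_svm <- function(x, y, C = 1e8, sigma2 = 1, tol = 1e-6,
                    quiet_passes = 10L, max_sweeps = 2000L, seed = 99L) {
  n <- nrow(x)
  kmat <- exp(-as.matrix(stats::dist(x))^2 / (2 * sigma2))
  alpha <- numeric(n)
  b <- 0
  set.seed(seed)
  passes <- 0L
  sweeps <- 0L
  err <- function(i) sum(alpha * y * kmat[, i]) + b - y[i]
  while (passes < quiet_passes && sweeps < max_sweeps) {
    changed <- 0L
    for (i in seq_len(n)) {
      ei <- err(i)
      if (!((y[i] * ei < -tol && alpha[i] < C) ||
            (y[i] * ei > tol && alpha[i] > 0))) next
      j <- sample(seq_len(n)[-i], 1L)
      ej <- err(j)
      ai0 <- alpha[i]; aj0 <- alpha[j]
      if (y[i] != y[j]) {
        lo <- max(0, aj0 - ai0); hi <- min(C, C + aj0 - ai0)
      } else {
        lo <- max(0, ai0 + aj0 - C); hi <- min(C, ai0 + aj0)
      }
      if (lo >= hi) next
      eta <- 2 * kmat[i, j] - kmat[i, i] - kmat[j, j]
      if (eta >= 0) next
      aj <- min(hi, max(lo, aj0 - y[j] * (ei - ej) / eta))
      if (abs(aj - aj0) < 1e-14) next
      ai <- ai0 + y[i] * y[j] * (aj0 - aj)
      b1 <- b - ei - y[i] * (ai - ai0) * kmat[i, i] -
        y[j] * (aj - aj0) * kmat[i, j]
      b2 <- b - ej - y[i] * (ai - ai0) * kmat[i, j] -
        y[j] * (aj - aj0) * kmat[j, j]
      alpha[i] <- ai; alpha[j] <- aj
      b <- if (ai > 0 && ai < C) b1
           else if (aj > 0 && aj < C) b2
           else (b1 + b2) / 2
      changed <- changed + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    sweeps <- sweeps + 1L
  }
  list(x = x, y = y, alpha = alpha, b = b, sigma2 = sigma2)
}

smo_decision <- function(model, newx) {
  d <- outer(rowSums(newx^2), rowSums(model$x^2), "+") -
    2 * tcrossprod(newx, model$x)
  d[d < 0] <- 0
  kmat <- exp(-d / (2 * model$sigma2))
  drop(kmat %*% (model$alpha * model$y)) + model$b
}
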