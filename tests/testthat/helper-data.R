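# Small in-code fixtures shared across tests.

# Two well-separated 2-D Gaussian blobs, labels +1 / -1.
two_blobs <- function(n_per = 10L, centers = rbind(c(0, 0), c(3, 3)),
                      sd = 0.5, seed = 1L) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per, centers[1, 1], sd), rnorm(n_per, centers[1, 2], sd)),
    cbind(rnorm(n_per, centers[2, 1], sd), rnorm(n_per, centers[2, 2], sd)))
  list(x = x, y = rep(c(1, -1), each = n_per))
}

# The printed fetal-state confusion matrix (counts, predicted x actual).
ctg_table5 <- function() {
  m <- matrix(c(1604, 38, 13,
                70, 208, 17,
                12, 29, 135), nrow = 3,
              dimnames = list(predicted = ctg_classes,
                              actual = ctg_classes))
  structure(m, class = "confusion_matrix")
}

# Random binary toy problem for property suites.
random_binary_problem <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- sign(x[, 1] + 0.3 * rnorm(n))
  y[y == 0] <- 1
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y)
}
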