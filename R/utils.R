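# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and an integer tag.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  s <- (as.double(seed) %% 2147483629) * 48271 + as.double(tag) * 16807
  as.integer(s %% 2147483629L)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = length(x))
  storage.mode(x) <- "double"
  x
}

check_finite <- function(x, what = "x") {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
row_sqdist <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0 # guard tiny negative round-off
  d
}
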