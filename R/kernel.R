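#' Gaussian radial basis kernel
#'
#' Evaluates \eqn{K(x, z) = \exp(-\|x - z\|^2 / (2\sigma^2))}, the only
#' kernel used by the LS-SVM classifiers in this package. `sigma2` is the
#' kernel width \eqn{\sigma^2}: larger values make the similarity decay more
#' slowly with squared distance.
#'
#' @param x,z Numeric vectors of equal length.
#' @param sigma2 Positive kernel width \eqn{\sigma^2}.
#' @return A scalar in (0, 1]; equals 1 iff `x == z`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma2 = 1) # exp(-1)
#' @export
rbf_kernel <- function(x, z, sigma2) {
  if (length(x) != length(z))
    stopf("dimension mismatch: length(x) = %d, length(z) = %d",
          length(x), length(z))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stopf("sigma2 must be a positive finite scalar (got %s)",
          format(sigma2))
  exp(-sum((x - z)^2) / (2 * sigma2))
}

# Kernel matrix between rows of a and rows of b (matrices), vectorized.
rbf_kernel_matrix <- function(a, b = a, sigma2) {
  exp(-row_sqdist(a, b) / (2 * sigma2))
}
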