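#' Count likelihoods and the Gaussian KL term
#'
#' Closed-form building blocks of the variational objective. The negative
#' binomial is parameterized by mean `mu` and inverse-dispersion `size`
#' (variance `mu + mu^2/size`); as `size` grows it approaches the Poisson.
#' All three functions return one value per cell (row), summing over
#' features for matrix input.
#'
#' @param x Non-negative integer counts: a vector (one cell) or a
#'   cells-by-features matrix.
#' @param mu,size Negative-binomial mean (same shape as `x`) and per-feature
#'   inverse-dispersion (scalar, vector of length `ncol(x)`, or full
#'   matrix); both must be positive (zero mean is allowed only where
#'   `x = 0`).
#' @param lambda Poisson rate, same shape rules as `mu`; non-negative.
#' @param mean,logvar Variational Gaussian mean and log-variance,
#'   cells-by-dimensions.
#' @return Numeric vector, one non-negative log-likelihood (or KL) per cell.
#' @examples
#' poissonNegLogLikelihood(1, 1)            # exactly 1
#' gaussianKL(matrix(1), matrix(0))         # exactly 0.5
#' @name likelihoods
NULL

#' @rdname likelihoods
#' @export
nbNegLogLikelihood <- function(x, mu, size) {
  x <- rbind(x); mu <- rbind(mu)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    .stopf("x must contain non-negative integer counts")
  if (any(size <= 0)) .stopf("size (inverse-dispersion) must be positive")
  if (any(mu < 0) || any(mu == 0 & x > 0))
    .stopf("mu must be positive wherever x > 0")
  if (length(size) == 1L || length(size) == ncol(x))
    size <- matrix(size, nrow(x), ncol(x), byrow = TRUE)
  ll <- lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
    size * (log(size) - log(size + mu))
  pos <- x > 0
  ll[pos] <- ll[pos] + x[pos] * (log(mu[pos]) - log(size[pos] + mu[pos]))
  unname(rowSums(-ll))
}

#' @rdname likelihoods
#' @export
poissonNegLogLikelihood <- function(x, lambda) {
  x <- rbind(x); lambda <- rbind(lambda)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    .stopf("x must contain non-negative integer counts")
  if (any(lambda < 0) || any(lambda == 0 & x > 0))
    .stopf("lambda must be non-negative (positive wherever x > 0)")
  nll <- lambda + lgamma(x + 1)
  pos <- x > 0
  nll[pos] <- nll[pos] - x[pos] * log(lambda[pos])
  unname(rowSums(nll))
}

#' @rdname likelihoods
#' @export
gaussianKL <- function(mean, logvar) {
  mean <- rbind(mean); logvar <- rbind(logvar)
  if (any(!is.finite(logvar))) .stopf("logvar must be finite")
  unname(0.5 * rowSums(mean^2 + exp(logvar) - 1 - logvar))
}
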