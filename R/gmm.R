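#' Construct a GaussianMixture
#'
#' @param weights nonnegative weights summing to 1.
#' @param means d x K matrix (columns are component means).
#' @param covariances d x d x K array.
#' @param pathLabels optional K x L integer matrix of layer indices.
#' @return a \linkS4class{GaussianMixture}.
#' @export
gaussianMixture <- function(weights, means, covariances, pathLabels = NULL) {
  if (is.vector(means)) means <- matrix(means, ncol = length(weights))
  if (length(dim(covariances)) == 2L)
    covariances <- array(covariances, c(dim(covariances), 1L))
  if (is.null(pathLabels)) pathLabels <- matrix(seq_along(weights), ncol = 1L)
  new("GaussianMixture", weights = weights, means = means,
      covariances = covariances, pathLabels = pathLabels)
}

#' Log-density of a Gaussian mixture
#'
#' Per-component Cholesky log-densities combined by log-sum-exp; components
#' with zero weight are skipped.
#'
#' @param gmm a \linkS4class{GaussianMixture}.
#' @param x a point (length-d vector) or an m x d matrix of points.
#' @return numeric vector of log-densities (length m).
#' @export
gmmLogpdf <- function(gmm, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  act <- which(gmm@weights > 0)
  lp <- matrix(-Inf, nrow(x), length(act))
  for (j in seq_along(act)) {
    k <- act[j]
    Sk <- gmm@covariances[, , k]
    if (!is.matrix(Sk)) Sk <- matrix(Sk, nrow(gmm@means), nrow(gmm@means))
    lp[, j] <- log(gmm@weights[k]) + mvnLogpdf(x, gmm@means[, k], Sk)
  }
  if (length(act) == 1L) as.numeric(lp) else rowLogSumExp(lp)
}

#' Mean and covariance of a Gaussian mixture
#'
#' mean = sum_k w_k mu_k; covariance = sum_k w_k (Sigma_k + mu_k mu_k') -
#' mean mean' (law of total variance).
#'
#' @param gmm a \linkS4class{GaussianMixture}.
#' @return list(mean, covariance).
#' @export
gmmMoments <- function(gmm) {
  w <- gmm@weights
  m <- as.numeric(gmm@means %*% w)
  d <- nrow(gmm@means)
  S <- matrix(0, d, d)
  for (k in which(w > 0)) {
    S <- S + w[k] * (gmm@covariances[, , k] + tcrossprod(gmm@means[, k]))
  }
  list(mean = m, covariance = S - tcrossprod(m))
}

#' CDF of a scalar Gaussian mixture
#'
#' @param weights component weights.
#' @param means component means.
#' @param variances component variances (positive).
#' @param threshold evaluation point(s).
#' @return sum_k w_k Phi((threshold - m_k)/s_k), vectorized over threshold.
#' @export
gmmScalarCdf <- function(weights, means, variances, threshold) {
  stopifnot(all(variances > 0))
  sds <- sqrt(variances)
  vapply(threshold, function(cc) sum(weights * stats::pnorm((cc - means) / sds)),
         numeric(1))
}

#' Quantile of a scalar Gaussian mixture (bisection)
#'
#' @param weights,means,variances mixture parameters.
#' @param p probability in (0, 1).
#' @param tol bisection tolerance on the abscissa.
#' @export
gmmScalarQuantile <- function(weights, means, variances, p, tol = 1e-10) {
  stopifnot(p > 0, p < 1)
  sds <- sqrt(variances)
  lo <- min(means - 10 * sds); hi <- max(means + 10 * sds)
  while (gmmScalarCdf(weights, means, variances, lo) > p) lo <- lo - (hi - lo)
  while (gmmScalarCdf(weights, means, variances, hi) < p) hi <- hi + (hi - lo)
  while (hi - lo > tol * max(1, abs(lo), abs(hi))) {
    mid <- (lo + hi) / 2
    if (gmmScalarCdf(weights, means, variances, mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Draw samples from a Gaussian mixture
#'
#' @param gmm a \linkS4class{GaussianMixture}.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return list with \code{x} (n x d matrix) and \code{component} (indices).
#' @export
sampleGMM <- function(gmm, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(gmm@means)
  k <- sample.int(length(gmm@weights), n, replace = TRUE, prob = gmm@weights)
  x <- matrix(0, n, d)
  for (kk in unique(k)) {
    idx <- which(k == kk)
    Sk <- gmm@covariances[, , kk]
    if (!is.matrix(Sk)) Sk <- matrix(Sk, d, d)
    R <- safeChol(Sk, label = "component covariance")
    x[idx, ] <- matrix(stats::rnorm(length(idx) * d), length(idx), d) %*% R +
      rep(gmm@means[, kk], each = length(idx))
  }
  list(x = x, component = k)
}
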