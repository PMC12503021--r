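#' Marginal log-likelihood of one subject
#'
#' Integrating the coefficient vector out of the regression layer against the
#' mixture prior gives the marginal
#' log sum_k w_k N(y_i; B_i mu_k, B_i Sigma_k B_i' + sigma2 I), computed via
#' per-component Cholesky densities and log-sum-exp. Valid for any n_i,
#' including n_i < d, n_i = 1 and n_i = 0 (the empty product, log-lik 0).
#'
#' @param y_i response vector (length n_i).
#' @param B_i n_i x d design matrix.
#' @param gmm \linkS4class{GaussianMixture} prior on the coefficients.
#' @param sigma2 error variance.
#' @return scalar log-likelihood.
#' @export
subjectMarginalLoglik <- function(y_i, B_i, gmm, sigma2) {
  stopifnot(sigma2 > 0)
  if (!is.matrix(B_i)) B_i <- matrix(B_i, nrow = length(y_i))
  if (nrow(B_i) != length(y_i) || ncol(B_i) != nrow(gmm@means))
    stop("shape error: design matrix is ", nrow(B_i), " x ", ncol(B_i),
         " but y has length ", length(y_i), " and prior dimension is ",
         nrow(gmm@means))
  ni <- length(y_i)
  if (ni == 0L) return(0)
  act <- which(gmm@weights > 0)
  lp <- numeric(length(act))
  for (j in seq_along(act)) {
    k <- act[j]
    Sk <- gmm@covariances[, , k]
    if (!is.matrix(Sk)) Sk <- matrix(Sk, ncol(B_i), ncol(B_i))
    S <- B_i %*% Sk %*% t(B_i) + diag(sigma2, ni)
    lp[j] <- log(gmm@weights[k]) + mvnLogpdf(y_i, as.numeric(B_i %*% gmm@means[, k]), S)
  }
  logSumExp(lp)
}

#' Complete-data log-likelihood of one subject
#'
#' @param y_i response vector.
#' @param B_i n_i x d design matrix.
#' @param beta_i coefficient vector (length d).
#' @param sigma2 error variance.
#' @return log N(y_i; B_i beta_i, sigma2 I).
#' @export
completeDataLoglik <- function(y_i, B_i, beta_i, sigma2) {
  if (!is.matrix(B_i)) B_i <- matrix(B_i, nrow = length(y_i))
  if (nrow(B_i) != length(y_i) || ncol(B_i) != length(beta_i))
    stop("shape error in completeDataLoglik")
  r <- y_i - as.numeric(B_i %*% beta_i)
  ni <- length(y_i)
  -0.5 * ni * log(2 * pi * sigma2) - sum(r^2) / (2 * sigma2)
}
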