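## Everything computed from a fitted model: conditional and marginal
## predictive mixtures, intervals, risks, coverage, clustering.

## Coerce a PredictiveGMM to a GaussianMixture over the query-time space so
## the mixture utilities (log-density, moments) apply.
asGaussianMixture <- function(pred) {
  new("GaussianMixture", weights = pred@weights, means = pred@means,
      covariances = pred@covariances,
      pathLabels = matrix(seq_along(pred@weights), ncol = 1L))
}

#' Conditional predictive distribution at new times
#'
#' The joint law of (observed, unobserved) responses under the fitted mixture
#' is a Gaussian mixture, so the conditional of the unobserved responses
#' given y_i is again a Gaussian mixture: with S_k = B_i Sigma_k B_i' +
#' sigma2 I, component weights are proportional to w_k N(y_i; B_i mu_k, S_k)
#' and means/covariances follow the standard Gaussian conditional (the
#' predictive covariance keeps its own sigma2 I term). Conditioning on
#' nothing (n_i = 0) returns the marginal predictive.
#'
#' @param model a \linkS4class{DMLMMFit}.
#' @param y_i observed responses (may be length 0).
#' @param t_i observation times (same length).
#' @param t_new query times.
#' @return a \linkS4class{PredictiveGMM}.
#' @export
conditionalPredictive <- function(model, y_i, t_i, t_new) {
  stopifnot(length(y_i) == length(t_i))
  gmm <- model@gmm
  s2 <- model@sigma2
  Bi <- designMatrix(model@basis, t_i)
  Bt <- designMatrix(model@basis, t_new)
  TT <- length(t_new)
  ni <- length(y_i)
  act <- which(gmm@weights > 0)
  Kact <- length(act)
  logw <- numeric(Kact)
  means <- matrix(0, TT, Kact)
  covs <- array(0, c(TT, TT, Kact))
  for (j in seq_len(Kact)) {
    k <- act[j]
    Sk <- gmm@covariances[, , k]
    if (!is.matrix(Sk)) Sk <- matrix(Sk, model@basis@d, model@basis@d)
    mu <- gmm@means[, k]
    if (ni == 0L) {
      logw[j] <- log(gmm@weights[k])
      means[, j] <- Bt %*% mu
      covs[, , j] <- Bt %*% Sk %*% t(Bt) + diag(s2, TT)
    } else {
      S <- Bi %*% Sk %*% t(Bi) + diag(s2, ni)
      resid <- y_i - as.numeric(Bi %*% mu)
      logw[j] <- log(gmm@weights[k]) + mvnLogpdf(y_i, as.numeric(Bi %*% mu), S)
      Rch <- safeChol(S, label = "conditioning covariance")
      CrossT <- Bi %*% Sk %*% t(Bt)               # n_i x T
      Sinv_cross <- backsolve(Rch, backsolve(Rch, CrossT, transpose = TRUE))
      Sinv_resid <- backsolve(Rch, backsolve(Rch, resid, transpose = TRUE))
      means[, j] <- as.numeric(Bt %*% mu) + as.numeric(crossprod(CrossT, Sinv_resid))
      V <- Bt %*% Sk %*% t(Bt) + diag(s2, TT) - crossprod(CrossT, Sinv_cross)
      covs[, , j] <- (V + t(V)) / 2
    }
  }
  w <- exp(logw - logSumExp(logw))
  new("PredictiveGMM", times = as.numeric(t_new), weights = w / sum(w),
      means = means, covariances = covs)
}

#' Marginal predictive distribution (no conditioning)
#'
#' @param model a \linkS4class{DMLMMFit}.
#' @param t_new query times.
#' @return a \linkS4class{PredictiveGMM}.
#' @export
marginalPredictive <- function(model, t_new) {
  conditionalPredictive(model, numeric(0), numeric(0), t_new)
}

#' Pointwise mean, variance and correlation of a predictive mixture
#'
#' @param pred a \linkS4class{PredictiveGMM}.
#' @return list(mean, variance, covariance, correlation) over the query grid.
#' @export
predictiveMoments <- function(pred) {
  mo <- gmmMoments(asGaussianMixture(pred))
  v <- diag(mo$covariance)
  list(mean = mo$mean, variance = v, covariance = mo$covariance,
       correlation = stats::cov2cor(mo$covariance))
}

#' Risk of the response falling below a threshold
#'
#' Mixture-of-Gaussian CDF of the predictive at one query time.
#'
#' @param pred a \linkS4class{PredictiveGMM}.
#' @param j query-time index.
#' @param threshold threshold c.
#' @return P(y_j <= c) under the predictive mixture.
#' @export
thresholdRisk <- function(pred, j, threshold) {
  stopifnot(j >= 1L, j <= length(pred@times))
  vars <- vapply(seq_along(pred@weights), function(k) pred@covariances[j, j, k],
                 numeric(1))
  gmmScalarCdf(pred@weights, pred@means[j, ], vars, threshold)
}

#' Equal-tailed pointwise credible intervals
#'
#' Per query time, the scalar mixture CDF is inverted by bisection.
#'
#' @param pred a \linkS4class{PredictiveGMM}.
#' @param level interval mass in (0, 1).
#' @return T x 2 matrix (lower, upper).
#' @export
pointwiseInterval <- function(pred, level = 0.95) {
  stopifnot(level > 0, level < 1)
  TT <- length(pred@times)
  out <- matrix(0, TT, 2, dimnames = list(NULL, c("lower", "upper")))
  for (j in seq_len(TT)) {
    vars <- vapply(seq_along(pred@weights), function(k) pred@covariances[j, j, k],
                   numeric(1))
    out[j, 1] <- gmmScalarQuantile(pred@weights, pred@means[j, ], vars, (1 - level) / 2)
    out[j, 2] <- gmmScalarQuantile(pred@weights, pred@means[j, ], vars, (1 + level) / 2)
  }
  out
}

#' Observed coverage of moment-matched elliptical credible sets
#'
#' The predictive mixture is moment-matched to a single Gaussian; coverage is
#' the fraction of truth samples inside the Mahalanobis ellipsoid at the
#' chi-squared quantile of the given level. For strongly multimodal
#' predictives this single-ellipsoid approximation undercovers.
#'
#' @param pred a \linkS4class{PredictiveGMM}.
#' @param level nominal level in [0, 1).
#' @param truth m x T matrix of truth samples.
#' @return observed coverage fraction.
#' @export
ellipticalSetCoverage <- function(pred, level, truth) {
  stopifnot(level >= 0, level < 1)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1L)
  if (level == 0) return(0)
  mo <- gmmMoments(asGaussianMixture(pred))
  TT <- length(mo$mean)
  R <- safeChol(mo$covariance, label = "moment-matched covariance")
  z <- backsolve(R, t(truth) - mo$mean, transpose = TRUE)
  d2 <- colSums(z^2)
  mean(d2 <= stats::qchisq(level, df = TT))
}

#' Implicit clustering of subjects
#'
#' Posterior path probabilities proportional to
#' w_k N(y_i; B_i mu_k, B_i Sigma_k B_i' + sigma2 I); the label is the argmax
#' path (ties broken by lowest index).
#'
#' @param model a \linkS4class{DMLMMFit}.
#' @param data a \linkS4class{LongitudinalData}.
#' @return list with \code{label} (integer component index per subject) and
#'   \code{probability} (n x K matrix; zero columns for pruned components).
#' @export
clusterAssign <- function(model, data) {
  gmm <- model@gmm
  K <- length(gmm@weights)
  act <- which(gmm@weights > 0)
  n <- nSubjects(data)
  prob <- matrix(0, n, K)
  for (i in seq_len(n)) {
    Bi <- designMatrix(model@basis, data@times[[i]])
    yi <- data@values[[i]]
    lp <- vapply(act, function(k) {
      Sk <- gmm@covariances[, , k]
      if (!is.matrix(Sk)) Sk <- matrix(Sk, model@basis@d, model@basis@d)
      S <- Bi %*% Sk %*% t(Bi) + diag(model@sigma2, length(yi))
      log(gmm@weights[k]) + mvnLogpdf(yi, as.numeric(Bi %*% gmm@means[, k]), S)
    }, numeric(1))
    prob[i, act] <- exp(lp - logSumExp(lp))
  }
  list(label = max.col(prob, ties.method = "first"), probability = prob)
}
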