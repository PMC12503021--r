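#' @import methods
NULL

#' Unbalanced longitudinal data
#'
#' Container for long-format longitudinal data: each subject i has an
#' observation-time vector t_i (length n_i, which may differ across subjects
#' and may be smaller than the basis dimension) and a response vector y_i of
#' the same length. Missingness is represented by absence of observations,
#' never by sentinel values.
#'
#' @slot ids character vector of subject identifiers (unique).
#' @slot times list of numeric vectors, one per subject.
#' @slot values list of numeric vectors, aligned with \code{times}.
#' @export
setClass("LongitudinalData",
  representation(ids = "character", times = "list", values = "list"),
  validity = function(object) {
    n <- length(object@ids)
    if (length(object@times) != n || length(object@values) != n)
      return("ids, times and values must have equal length")
    if (anyDuplicated(object@ids)) return("subject ids must be unique")
    for (i in seq_len(n)) {
      ti <- object@times[[i]]; yi <- object@values[[i]]
      if (length(ti) < 1L) return(sprintf("subject %s has no observations", object@ids[i]))
      if (length(ti) != length(yi))
        return(sprintf("subject %s: times and values differ in length", object@ids[i]))
      if (!all(is.finite(ti))) return(sprintf("subject %s has non-finite times", object@ids[i]))
    }
    TRUE
  })

#' Basis specification for the regression design matrix
#'
#' Describes how observation times map to a d-dimensional row of basis
#' evaluations. Supported kinds: \code{"legendre"} (Legendre polynomials of
#' degrees 0..d-1 on the domain affinely rescaled to [-1, 1]) and
#' \code{"bspline_seasonal"} (periodic cubic B-splines of a given period
#' concatenated with cubic B-splines over the whole domain).
#'
#' @slot kind "legendre" or "bspline_seasonal".
#' @slot d basis dimension.
#' @slot domain numeric length-2, (t_min, t_max).
#' @slot period seasonal period (NA unless seasonal).
#' @slot nSeasonal number of periodic spline columns.
#' @slot nTrend number of trend spline columns (nSeasonal + nTrend = d).
#' @export
setClass("BasisSpec",
  representation(kind = "character", d = "integer", domain = "numeric",
                 period = "numeric", nSeasonal = "integer", nTrend = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("legendre", "bspline_seasonal"))
      return("kind must be 'legendre' or 'bspline_seasonal'")
    if (object@d < 1L) return("d must be >= 1")
    if (length(object@domain) != 2L || !(object@domain[1] < object@domain[2]))
      return("domain must be (t_min, t_max) with t_min < t_max")
    if (object@kind == "bspline_seasonal") {
      if (!is.finite(object@period) || object@period <= 0) return("period must be positive")
      if (object@nSeasonal < 1L || object@nTrend < 0L) return("nSeasonal >= 1, nTrend >= 0")
      if (object@nSeasonal + object@nTrend != object@d)
        return("nSeasonal + nTrend must equal d")
    }
    TRUE
  })

#' Architecture of a deep mixture of factor analyzers
#'
#' Layer dimensions D = (D0, ..., DL) with D0 = d and per-layer component
#' counts K = (K1, ..., KL). Construction enforces the Anderson-Rubin
#' identifiability condition D(l+1) <= (D(l) - 1) / 2 for every consecutive
#' pair of dimensions.
#'
#' @slot D integer vector of layer dimensions, length L + 1.
#' @slot K integer vector of per-layer mixture sizes, length L.
#' @export
setClass("DMFAArchitecture",
  representation(D = "integer", K = "integer"),
  validity = function(object) {
    L <- length(object@K)
    if (L < 1L) return("need at least one layer")
    if (length(object@D) != L + 1L) return("D must have length L + 1")
    if (any(object@D < 1L) || any(object@K < 1L)) return("dimensions and counts must be >= 1")
    for (l in seq_len(L)) {
      if (object@D[l + 1L] > (object@D[l] - 1) / 2)
        return(sprintf(
          "Anderson-Rubin condition violated at layer %d: D(%d)=%d > (D(%d)-1)/2 = %.1f",
          l, l, object@D[l + 1L], l - 1L, (object@D[l] - 1) / 2))
    }
    TRUE
  })

#' Finite Gaussian mixture over the random-effect space
#'
#' Explicit mixture representation with one component per path through the
#' layered prior: weights, mean vectors and covariance matrices, plus the
#' per-component path labels (one mixture index per layer).
#'
#' @slot weights numeric vector, nonnegative, summing to 1 (zeros allowed after
#'   pruning).
#' @slot means d x K matrix of component means (columns are components).
#' @slot covariances d x d x K array of component covariances.
#' @slot pathLabels K x L integer matrix of per-layer component indices.
#' @export
setClass("GaussianMixture",
  representation(weights = "numeric", means = "matrix",
                 covariances = "array", pathLabels = "matrix"),
  validity = function(object) {
    K <- length(object@weights)
    if (any(object@weights < -1e-12)) return("weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-10) return("weights must sum to 1")
    if (ncol(object@means) != K) return("means must have one column per component")
    dd <- dim(object@covariances)
    if (length(dd) != 3L || dd[3] != K || dd[1] != dd[2] || dd[1] != nrow(object@means))
      return("covariances must be d x d x K")
    for (k in seq_len(K)) {
      S <- object@covariances[, , k]
      S <- (S + t(S)) / 2
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8) return(sprintf("component %d covariance is not PSD", k))
    }
    if (nrow(object@pathLabels) != K) return("pathLabels must have one row per component")
    TRUE
  })

#' Fitted deep mixture of linear mixed models
#'
#' Plug-in representation of a fitted model: the collapsed (and pruned)
#' Gaussian-mixture prior for the basis coefficients evaluated at the
#' variational posterior mean, the point estimate of the error variance, the
#' basis specification and architecture used, and fit diagnostics.
#'
#' @slot gmm collapsed \linkS4class{GaussianMixture} over the coefficient space.
#' @slot sigma2 error-variance point estimate.
#' @slot basis \linkS4class{BasisSpec} stored with the model.
#' @slot architecture \linkS4class{DMFAArchitecture}.
#' @slot elboTrace numeric matrix (iteration, elbo) of minibatch/full ELBO values.
#' @slot responsibilities n x K matrix of per-subject path probabilities at
#'   convergence (may have 0 rows for loaded models).
#' @slot seed integer seed the fit was run with.
#' @export
setClass("DMLMMFit",
  representation(gmm = "GaussianMixture", sigma2 = "numeric", basis = "BasisSpec",
                 architecture = "DMFAArchitecture", elboTrace = "matrix",
                 responsibilities = "matrix", seed = "integer"),
  validity = function(object) {
    if (length(object@sigma2) != 1L || object@sigma2 <= 0) return("sigma2 must be a positive scalar")
    TRUE
  })

#' Conditional or marginal predictive Gaussian mixture
#'
#' Distribution of unobserved responses at query times, either conditional on
#' a subject's observed responses or marginal (no conditioning). A mixture of
#' T-variate Gaussians whose covariances include the observation-noise term.
#'
#' @slot times numeric vector of query times (length T).
#' @slot weights component weights, summing to 1.
#' @slot means T x K matrix of component means.
#' @slot covariances T x T x K array.
#' @export
setClass("PredictiveGMM",
  representation(times = "numeric", weights = "numeric",
                 means = "matrix", covariances = "array"),
  validity = function(object) {
    if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
    if (nrow(object@means) != length(object@times)) return("means rows must match times")
    if (ncol(object@means) != length(object@weights)) return("means cols must match weights")
    TRUE
  })

setMethod("show", "LongitudinalData", function(object) {
  ni <- lengths(object@times)
  cat(sprintf("LongitudinalData: %d subjects, %d observations (n_i %d..%d)\n",
              length(object@ids), sum(ni), min(ni), max(ni)))
})

setMethod("show", "BasisSpec", function(object) {
  cat(sprintf("BasisSpec: %s, d = %d, domain [%g, %g]", object@kind, object@d,
              object@domain[1], object@domain[2]))
  if (object@kind == "bspline_seasonal")
    cat(sprintf(", period %g (%d seasonal + %d trend)", object@period,
                object@nSeasonal, object@nTrend))
  cat("\n")
})

setMethod("show", "DMFAArchitecture", function(object) {
  cat(sprintf("DMFAArchitecture: L = %d, D = (%s), K = (%s), %d paths\n",
              length(object@K), paste(object@D, collapse = ", "),
              paste(object@K, collapse = ", "), prod(object@K)))
})

setMethod("show", "GaussianMixture", function(object) {
  cat(sprintf("GaussianMixture: %d components (%d active), dimension %d\n",
              length(object@weights), sum(object@weights > 0), nrow(object@means)))
})

setMethod("show", "DMLMMFit", function(object) {
  cat("DMLMMFit\n")
  show(object@basis); show(object@architecture); show(object@gmm)
  cat(sprintf("  sigma2 = %.4g; final ELBO %.4g\n", object@sigma2,
              if (nrow(object@elboTrace)) object@elboTrace[nrow(object@elboTrace), 2] else NA))
})

setMethod("show", "PredictiveGMM", function(object) {
  cat(sprintf("PredictiveGMM: %d query times, %d components\n",
              length(object@times), length(object@weights)))
})
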