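#' Prior hyperparameters for the DMLMM
#'
#' Weakly informative defaults: half-Cauchy scale A on the response-scale
#' error sd, Cauchy scale c_mu on component mean entries, unit half-Cauchy
#' global scale for the horseshoe on factor loadings, and a small Dirichlet
#' concentration so that overfitted mixtures can empty superfluous
#' components.
#'
#' @param A half-Cauchy scale of the error sd sigma.
#' @param c_mu Cauchy scale for component mean entries.
#' @param hs_scale global half-Cauchy scale of the horseshoe on loadings.
#' @param alpha Dirichlet concentration for each layer's weights.
#' @param A_delta half-Cauchy scale for layer noise sds (defaults to A).
#' @return list of class "dmlmmPrior".
#' @export
dmlmmPrior <- function(A = 5, c_mu = 2.5, hs_scale = 1, alpha = 0.5, A_delta = A) {
  stopifnot(A > 0, c_mu > 0, hs_scale > 0, alpha > 0, A_delta > 0)
  structure(list(A = A, c_mu = c_mu, hs_scale = hs_scale, alpha = alpha,
                 A_delta = A_delta), class = "dmlmmPrior")
}

#' Log prior density of the error variance hierarchy
#'
#' The half-Cauchy prior sigma ~ HC(A) in its conjugacy-friendly hierarchical
#' form: sigma2 | psi ~ IG(1/2, 1/psi), psi ~ IG(1/2, 1/A^2)
#' (shape-rate parameterization).
#'
#' @param sigma2 error variance (> 0).
#' @param psi auxiliary scale (> 0).
#' @param A half-Cauchy scale (> 0).
#' @return joint log-density log p(sigma2 | psi) + log p(psi).
#' @export
logPriorSigma <- function(sigma2, psi, A) {
  if (sigma2 <= 0 || psi <= 0 || A <= 0) stop("domain error: all arguments must be positive")
  igLogpdf(sigma2, 0.5, 1 / psi) + igLogpdf(psi, 0.5, 1 / A^2)
}

## Free (lower-triangular) entry mask of a p x q loading matrix.
lowerTriMask <- function(p, q) {
  outer(seq_len(p), seq_len(q), ">=")
}

#' Log prior density of the DMFA parameters (hierarchical representation)
#'
#' Sums, over layers and components: elementwise Cauchy(0, c_mu) on the mean
#' shifts (normal-inverse-gamma mixture with auxiliaries tau_mu), half-Cauchy
#' on the noise sds (IG-IG, auxiliaries a_delta), the horseshoe on free
#' loading entries (normal with local lambda2 and per-layer global tau2
#' scales, each with its own IG auxiliary), and Dirichlet(alpha) on each
#' layer's weights.
#'
#' @param params a DMFAParameters object.
#' @param aux list of length L; element l has fields \code{tau_mu} (p x K),
#'   \code{a_delta} (p x K), \code{lambda2}, \code{nu} (lists of p x q
#'   matrices, free entries used), \code{tau2}, \code{xi} (scalars).
#' @param hp a \code{dmlmmPrior}.
#' @return scalar log prior density.
#' @export
logPriorDMFA <- function(params, aux, hp) {
  arch <- params$arch
  L <- length(arch@K)
  lp <- 0
  for (l in seq_len(L)) {
    lay <- params$layers[[l]]
    ax <- aux[[l]]
    p <- arch@D[l]; q <- arch@D[l + 1L]; K <- arch@K[l]
    mask <- lowerTriMask(p, q)
    if (any(ax$tau_mu <= 0) || any(ax$a_delta <= 0) || ax$tau2 <= 0 || ax$xi <= 0)
      stop("domain error: auxiliary scales must be positive")
    ## Dirichlet weights
    lp <- lp + dirichletLogC(rep(hp$alpha, K)) + sum((hp$alpha - 1) * log(lay$w))
    for (k in seq_len(K)) {
      ## Cauchy means: mu | tau ~ N(0, tau), tau ~ IG(1/2, c_mu^2/2)
      lp <- lp + sum(stats::dnorm(lay$mu[, k], 0, sqrt(ax$tau_mu[, k]), log = TRUE)) +
        sum(igLogpdf(ax$tau_mu[, k], 0.5, hp$c_mu^2 / 2))
      ## half-Cauchy noise sds: delta | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/A_delta^2)
      lp <- lp + sum(igLogpdf(lay$delta[, k], 0.5, 1 / ax$a_delta[, k])) +
        sum(igLogpdf(ax$a_delta[, k], 0.5, 1 / hp$A_delta^2))
      ## horseshoe loadings (free entries only)
      b <- lay$B[[k]][mask]
      l2 <- ax$lambda2[[k]][mask]
      nu <- ax$nu[[k]][mask]
      if (any(l2 <= 0) || any(nu <= 0)) stop("domain error: horseshoe scales must be positive")
      lp <- lp + sum(stats::dnorm(b, 0, sqrt(l2 * ax$tau2), log = TRUE)) +
        sum(igLogpdf(l2, 0.5, 1 / nu)) + sum(igLogpdf(nu, 0.5, 1))
    }
    lp <- lp + igLogpdf(ax$tau2, 0.5, 1 / ax$xi) + igLogpdf(ax$xi, 0.5, 1 / hp$hs_scale^2)
  }
  lp
}
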