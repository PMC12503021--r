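#' Control settings for variational fitting
#'
#' @param iterations number of outer stochastic-gradient iterations M.
#' @param minibatch minibatch size (capped at n; full batch when >= n).
#' @param n_inner cap on inner coordinate-ascent sweeps for local factors.
#' @param inner_tol per-subject local-ELBO convergence tolerance.
#' @param kappa,tau Robbins-Monro step-size schedule rho_m = (m + tau)^(-kappa).
#' @param step "auto" (unit steps when full batch, Robbins-Monro otherwise),
#'   "unit", or "robbins_monro".
#' @param seed integer seed; all randomness in the fit flows from it.
#' @param elbo_every compute the full-data ELBO every this many iterations
#'   (0 disables checkpoints; final ELBO is always computed).
#' @param verbose log progress lines to stderr every 50 iterations.
#' @return list of class "dmlmmControl".
#' @export
dmlmmControl <- function(iterations = 1000L, minibatch = 64L, n_inner = 20L,
                         inner_tol = 1e-8, kappa = 0.75, tau = 10,
                         step = c("auto", "unit", "robbins_monro"),
                         seed = 1L, elbo_every = 0L, verbose = FALSE) {
  step <- match.arg(step)
  stopifnot(iterations >= 1L, minibatch >= 1L, n_inner >= 1L)
  structure(list(iterations = as.integer(iterations), minibatch = as.integer(minibatch),
                 n_inner = as.integer(n_inner), inner_tol = inner_tol,
                 kappa = kappa, tau = tau, step = step, seed = as.integer(seed),
                 elbo_every = as.integer(elbo_every), verbose = verbose),
            class = "dmlmmControl")
}

#' Initialize the variational state
#'
#' Coefficient factors start at ridge projections of y_i onto the design
#' (penalty 1e-3 I, so n_i < d is fine); first-layer responsibilities come
#' from k-means on the ridge coefficients; deeper layers start uniform;
#' loadings from per-cluster principal directions with unit column norm;
#' noise and error variances from ridge residuals. Deterministic given the
#' seed in \code{control}.
#'
#' @param cache data cache from \code{buildDataCache}.
#' @param arch a \linkS4class{DMFAArchitecture}.
#' @param prior a \code{dmlmmPrior}.
#' @param control a \code{dmlmmControl}.
#' @return state environment (internal representation).
#' @keywords internal
initState <- function(cache, arch, prior, control) {
  validObject(arch)
  set.seed(childSeed(control$seed, 101L))
  n <- cache$n; d <- cache$d; L <- length(arch@K)
  if (n < prod(arch@K))
    warning("fewer subjects (", n, ") than mixture paths (", prod(arch@K),
            "); overfitted mixture expected to prune")
  st <- new.env(parent = emptyenv())
  st$arch <- arch; st$prior <- prior; st$control <- control
  st$n <- n; st$d <- d; st$L <- L
  st$lc <- vector("list", L)

  ## ridge projections: a near-unpenalized one (1e-3 I) seeds the coefficient
  ## factors; a moderately penalized one (scaled to the average design
  ## information) seeds clustering and per-cluster parameters, since the
  ## unpenalized projections oscillate wildly in directions the observation
  ## pattern leaves ill-conditioned.
  beta0 <- matrix(0, n, d)
  betas <- matrix(0, n, d)
  resvar <- numeric(n)
  lam_s <- 0.1 * mean(apply(cache$BtB, 3, function(M) mean(diag(M))))
  for (i in seq_len(n)) {
    beta0[i, ] <- solve(cache$BtB[, , i] + diag(1e-3, d), cache$Bty[, i])
    b <- solve(cache$BtB[, , i] + diag(lam_s, d), cache$Bty[, i])
    betas[i, ] <- b
    ni <- cache$ni[i]
    rss <- cache$yty[i] - 2 * sum(cache$Bty[, i] * b) + sum(b * (cache$BtB[, , i] %*% b))
    resvar[i] <- max(rss, 0) / max(ni, 1L)
  }
  sigma20 <- max(mean(resvar), 1e-4)

  ## k-means on the initialized coefficient means for layer-1
  ## responsibilities. Distances are taken between the implied smooth curves
  ## (coefficients mapped through the basis on a fine grid), which whitens
  ## coefficient directions that the observation pattern leaves
  ## ill-conditioned.
  K1 <- arch@K[1]
  Fmat <- betas %*% t(cache$Bgrid)
  km <- if (K1 > 1L && n > K1) {
    kmc <- stats::kmeans(Fmat, centers = K1, nstart = 10L, iter.max = 100L)
    list(cluster = kmc$cluster)
  } else list(cluster = rep(1L, n))
  r1 <- matrix(0.02 / max(K1 - 1L, 1L), n, K1)
  r1[cbind(seq_len(n), km$cluster)] <- if (K1 > 1L) 0.98 else 1
  r1 <- r1 / rowSums(r1)

  ## locals
  st$loc <- list(
    beta_m = beta0, beta_v = matrix(0.1, n, d),
    z_m = lapply(seq_len(L), function(l) matrix(0, n, arch@D[l + 1L])),
    z_v = lapply(seq_len(L), function(l) matrix(1, n, arch@D[l + 1L])),
    r = c(list(r1), lapply(seq_len(L)[-1L],
                           function(l) matrix(1 / arch@K[l], n, arch@K[l]))))

  ## global factors, layer by layer. Each layer is seeded from a clustering of
  ## its input scores (layer 1: the k-means partition above; deeper layers:
  ## k-means on the previous layer's principal-component scores), with
  ## loadings from per-cluster principal directions (unit column norm) and
  ## factor-score locals set to the corresponding projections.
  st$g <- list(layers = vector("list", L))
  X <- betas                              # layer input scores (n x D(l-1))
  for (l in seq_len(L)) {
    p <- arch@D[l]; q <- arch@D[l + 1L]; K <- arch@K[l]
    cl <- if (l == 1L) km$cluster
    else if (K > 1L && n > K) stats::kmeans(X, centers = K, nstart = 10L,
                                            iter.max = 100L)$cluster
    else rep(1L, n)
    mu0 <- matrix(0, p, K); del0 <- matrix(1, p, K)
    Bm <- vector("list", K); BS <- vector("list", K)
    scores <- matrix(0, n, q)
    ## probabilistic-PCA seeding of the loadings: principal directions of the
    ## pooled within-cluster residuals, shared across components so that the
    ## factor space has one orientation (deeper layers then see comparable
    ## scores), with per-component scales; noise is the per-dimension
    ## variance left over after the retained directions.
    for (k in seq_len(K)) {
      members <- which(cl == k)
      mu0[, k] <- if (length(members)) colMeans(X[members, , drop = FALSE]) else
        colMeans(X) + stats::rnorm(p, 0, 0.1)
    }
    Rall <- X - t(mu0)[cl, , drop = FALSE]
    svg <- svd(Rall, nu = 0)
    lamg <- svg$d^2 / max(n - 1L, 1L)
    qq <- min(q, ncol(svg$v))
    Vg <- svg$v[, seq_len(qq), drop = FALSE]
    floorvar <- if (length(lamg) > qq) mean(lamg[-seq_len(qq)]) else 1e-3
    for (k in seq_len(K)) {
      members <- which(cl == k)
      Bk <- matrix(stats::rnorm(p * q, 0, 0.1), p, q)
      if (length(members) > max(q, 1L)) {
        resid <- sweep(X[members, , drop = FALSE], 2, mu0[, k])
        proj <- resid %*% Vg
        sc <- sqrt(pmax(apply(proj, 2, stats::var) - floorvar, 1e-4))
        Bk[, seq_len(qq)] <- sweep(Vg, 2, sc, `*`)
        scores[members, seq_len(qq)] <- sweep(proj, 2, sc, `/`)
        del0[, k] <- pmax(colMeans((resid - proj %*% t(Vg))^2), 1e-3)
      }
      ## enforce the lower-triangular free pattern
      Bk[!lowerTriMask(p, q)] <- 0
      Bm[[k]] <- Bk
      BS[[k]] <- lapply(seq_len(p), function(j) diag(1e-2, min(j, q)))
    }
    st$loc$z_m[[l]] <- scores
    st$loc$z_v[[l]] <- matrix(0.1, n, q)
    X <- scores
    Nk <- pmax(colSums(st$loc$r[[l]]), 1e-3)
    st$g$layers[[l]] <- list(
      dirichlet = prior$alpha + Nk,
      mu_m = mu0, mu_v = matrix(1e-2, p, K),
      B_m = Bm, B_S = BS,
      delta_a = 0.5 + Nk / 2,
      delta_b = sweep(del0, 2, 0.5 + Nk / 2, `*`),
      a_delta_b = 1 / prior$A_delta^2 + 1 / del0,
      tau_mu_b = prior$c_mu^2 / 2 + (mu0^2 + 1e-2) / 2,
      lam_b = lapply(Bm, function(B) 1 + (B^2) / 2),
      nu_b = lapply(Bm, function(B) matrix(2, p, q)),
      tau2 = c(a = (1 + freeCount(p, q) * K) / 2, b = (1 + freeCount(p, q) * K) / 2),
      xi_b = 1 / prior$hs_scale^2 + 1)
    refreshLayerCache(st, l)
  }
  st$g$sigma2 <- c(a = 0.5 + cache$Ntot / 2, b = (0.5 + cache$Ntot / 2) * sigma20)
  st$g$psi <- c(a = 1, b = 1 / prior$A^2 + 1 / sigma20)
  refreshSigmaCache(st)
  st
}
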