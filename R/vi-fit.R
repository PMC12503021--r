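## The outer stochastic variational loop and post-fit collapse/pruning.

## Per-subject posterior path probabilities: product over layers of the
## per-layer responsibilities, in the lexicographic path order used by
## collapseToGMM.
pathResponsibilities <- function(r, K) {
  paths <- enumeratePaths(K)
  n <- nrow(r[[1L]])
  out <- matrix(1, n, nrow(paths))
  for (l in seq_along(K)) out <- out * r[[l]][, paths[, l], drop = FALSE]
  out
}

## Posterior-mean point estimate of the collapsed mixture. The plug-in
## estimate targets the GMM parameters (w_k, mu_k, Sigma_k) themselves, so
## Sigma_k is the exact q-expectation of the collapsed covariance, which
## under the independent factors is a backward recursion
## C(l-1) = E[delta(l)] + E[B(l) C(l) B(l)'] with
## E[B C B']_(jj') = mB_j C mB_j' + 1{j = j'} tr(C_sub SigmaB_j).
posteriorMeanGMM <- function(st) {
  arch <- st$arch
  L <- st$L
  d <- arch@D[1L]
  paths <- enumeratePaths(arch@K)
  Ktot <- nrow(paths)
  Edelta <- vector("list", L); wmean <- vector("list", L)
  for (l in seq_len(L)) {
    gl <- st$g$layers[[l]]
    a <- gl$delta_a
    Edelta[[l]] <- sweep(gl$delta_b, 2, ifelse(a > 1.01, a - 1, a), `/`)
    wmean[[l]] <- gl$dirichlet / sum(gl$dirichlet)
  }
  expectedBCB <- function(gl, k, C) {
    p <- nrow(gl$mu_m); q <- ncol(C)
    mB <- gl$B_m[[k]]
    out <- mB %*% C %*% t(mB)
    for (j in seq_len(p)) {
      f <- min(j, q); sf <- seq_len(f)
      out[j, j] <- out[j, j] + sum(C[sf, sf] * gl$B_S[[k]][[j]])
    }
    out
  }
  w <- numeric(Ktot); means <- matrix(0, d, Ktot); covs <- array(0, c(d, d, Ktot))
  for (k in seq_len(Ktot)) {
    C <- diag(1, arch@D[L + 1L])
    u <- numeric(arch@D[L + 1L])
    wk <- 1
    for (l in L:1) {
      gl <- st$g$layers[[l]]
      kl <- paths[k, l]
      wk <- wk * wmean[[l]][kl]
      C <- diag(Edelta[[l]][, kl], arch@D[l]) + expectedBCB(gl, kl, C)
      u <- gl$mu_m[, kl] + as.numeric(gl$B_m[[kl]] %*% u)
    }
    w[k] <- wk
    means[, k] <- u
    covs[, , k] <- (C + t(C)) / 2
  }
  new("GaussianMixture", weights = w / sum(w), means = means, covariances = covs,
      pathLabels = paths)
}

#' Zero out empty mixture components and rescale
#'
#' A path component is empty when no subject has it as its argmax path
#' responsibility; empty components get weight zero, the remaining weights
#' are rescaled to sum to one, and means/covariances are untouched.
#'
#' @param gmm a \linkS4class{GaussianMixture}.
#' @param responsibilities n x K matrix of per-subject path probabilities.
#' @param min_count components with fewer argmax subjects than this are
#'   emptied (default 1, i.e. zero-assignment components).
#' @return the pruned \linkS4class{GaussianMixture}.
#' @export
pruneEmptyComponents <- function(gmm, responsibilities, min_count = 1L) {
  K <- length(gmm@weights)
  stopifnot(ncol(responsibilities) == K)
  lab <- max.col(responsibilities, ties.method = "first")
  counts <- tabulate(lab, nbins = K)
  keep <- counts >= min_count
  if (!any(keep)) stop("all components empty; cannot prune")
  w <- gmm@weights
  w[!keep] <- 0
  w <- w / sum(w)
  methods::initialize(gmm, weights = w)
}

#' Fit a deep mixture of linear mixed models
#'
#' Runs M outer iterations of: sample a minibatch, optimize that minibatch's
#' local factors by coordinate ascent, take a natural-gradient step on all
#' global factors. Afterwards a full-data local pass is run, empty path
#' components are pruned, and the posterior-mean parameters are collapsed to
#' an explicit Gaussian mixture with the q-mean of sigma2 as the error
#' variance. Deterministic given \code{control$seed}.
#'
#' @param data a \linkS4class{LongitudinalData}.
#' @param architecture a \linkS4class{DMFAArchitecture} with D[1] = basis
#'   dimension.
#' @param basis a \linkS4class{BasisSpec}; defaults to Legendre polynomials of
#'   dimension D[1] on the observed time range.
#' @param prior a \code{dmlmmPrior}.
#' @param control a \code{dmlmmControl}.
#' @return a \linkS4class{DMLMMFit}.
#' @export
fitDMLMM <- function(data, architecture, basis = NULL,
                     prior = dmlmmPrior(), control = dmlmmControl()) {
  stopifnot(is(data, "LongitudinalData"), is(architecture, "DMFAArchitecture"))
  if (is.null(basis)) {
    rng <- range(unlist(data@times))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    basis <- legendreBasis(architecture@D[1], rng)
  }
  if (basis@d != architecture@D[1])
    stop("basis dimension (", basis@d, ") must equal architecture D[1] (",
         architecture@D[1], ")")
  cache <- buildDataCache(data, basis)
  st <- initState(cache, architecture, prior, control)
  n <- cache$n
  mb <- min(control$minibatch, n)
  unit <- control$step == "unit" || (control$step == "auto" && mb == n)
  set.seed(childSeed(control$seed, 202L))
  trace <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("iteration", "elbo")))
  order_pool <- integer(0)
  for (m in seq_len(control$iterations)) {
    if (mb == n) idx <- seq_len(n)
    else {
      if (length(order_pool) < mb) order_pool <- sample.int(n)
      idx <- order_pool[seq_len(mb)]
      order_pool <- order_pool[-seq_len(mb)]
    }
    obj <- updateLocalsBatch(st, cache, idx)
    rho <- if (unit) 1 else (m + control$tau)^(-control$kappa)
    naturalGradientGlobalStep(st, cache, idx, rho)
    if (control$elbo_every > 0L && m %% control$elbo_every == 0L) {
      e <- elboState(st, cache)$total
      trace <- rbind(trace, c(m, e))
      if (control$verbose) message(sprintf("iter %d: full-data ELBO %.4f", m, e))
    } else if (control$verbose && m %% 50L == 0L) {
      message(sprintf("iter %d: minibatch objective %.4f", m, (n / mb) * obj))
    }
  }
  ## full-data local pass, final ELBO, prune, collapse
  updateLocalsBatch(st, cache, seq_len(n))
  final <- elboState(st, cache)$total
  trace <- rbind(trace, c(control$iterations + 1L, final))
  pathR <- pathResponsibilities(st$loc$r, architecture@K)
  gmm <- posteriorMeanGMM(st)
  gmm <- pruneEmptyComponents(gmm, pathR)
  sigma2 <- st$g$sigma2[["b"]] / (st$g$sigma2[["a"]] - 1)
  fit <- new("DMLMMFit", gmm = gmm, sigma2 = sigma2, basis = basis,
             architecture = architecture, elboTrace = trace,
             responsibilities = pathR, seed = control$seed)
  attr(fit, "state") <- st
  fit
}

#' Rank candidate architectures by short-run ELBO
#'
#' Fits each candidate for a small number of outer iterations under the same
#' seed schedule and ranks by the resulting full-data ELBO (descending);
#' ties are broken by fewer free parameters, then input order.
#'
#' @param data a \linkS4class{LongitudinalData}.
#' @param candidates list of \linkS4class{DMFAArchitecture} objects.
#' @param short_iters outer iterations per candidate.
#' @param basis,prior,control as in \code{fitDMLMM}.
#' @return data.frame with columns candidate (index), elbo, nparams, ordered
#'   best first.
#' @export
selectArchitecture <- function(data, candidates, short_iters = 50L, basis = NULL,
                               prior = dmlmmPrior(), control = dmlmmControl()) {
  if (!length(candidates)) stop("config error: empty candidate list")
  res <- data.frame(candidate = seq_along(candidates), elbo = NA_real_,
                    nparams = NA_integer_)
  for (j in seq_along(candidates)) {
    arch <- candidates[[j]]
    validObject(arch)
    ctrl <- control
    ctrl$iterations <- as.integer(short_iters)
    fit <- fitDMLMM(data, arch, basis = basis, prior = prior, control = ctrl)
    res$elbo[j] <- fit@elboTrace[nrow(fit@elboTrace), 2]
    res$nparams[j] <- sum(vapply(seq_along(arch@K), function(l) {
      p <- arch@D[l]; q <- arch@D[l + 1L]
      arch@K[l] * (2L * p + freeCount(p, q)) + (arch@K[l] - 1L)
    }, integer(1)))
  }
  res[order(-res$elbo, res$nparams, res$candidate), , drop = FALSE]
}
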