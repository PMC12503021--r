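#' Construct (and validate) a DMFA architecture
#'
#' @param D layer dimensions (D0 = basis dimension d, then latent dimensions).
#' @param K per-layer component counts.
#' @return a \linkS4class{DMFAArchitecture}; violations of the Anderson-Rubin
#'   dimension condition D(l+1) <= (D(l)-1)/2 are rejected with the offending
#'   layer named.
#' @export
dmfaArchitecture <- function(D, K) {
  new("DMFAArchitecture", D = as.integer(D), K = as.integer(K))
}

#' Validate a DMFA architecture
#'
#' @param arch a \linkS4class{DMFAArchitecture} (or D, K pair via
#'   \code{dmfaArchitecture}).
#' @return the architecture, invisibly, if valid; otherwise an error.
#' @export
validateArchitecture <- function(arch) {
  validObject(arch)
  invisible(arch)
}

#' Parameters of a deep mixture of factor analyzers
#'
#' Generative recursion: the coefficient vector is z(0); for l = 1..L,
#' z(l-1) = mu_k(l) + B_k(l) z(l) + eps with eps ~ N(0, delta_k(l)) and the
#' component k picked with probability w_k(l); at the top layer
#' z(L) ~ N(0, I).
#'
#' @param arch a \linkS4class{DMFAArchitecture}.
#' @param layers list of length L; element l is a list with fields
#'   \code{w} (K_l weights summing to 1), \code{mu} (D(l-1) x K_l matrix),
#'   \code{B} (list of K_l lower-triangular D(l-1) x D(l) matrices),
#'   \code{delta} (D(l-1) x K_l matrix of positive diagonal noise variances).
#' @return validated list of class "DMFAParameters" (arch + layers).
#' @export
dmfaParameters <- function(arch, layers) {
  validObject(arch)
  L <- length(arch@K)
  stopifnot(length(layers) == L)
  for (l in seq_len(L)) {
    p <- arch@D[l]; q <- arch@D[l + 1L]; K <- arch@K[l]
    lay <- layers[[l]]
    if (abs(sum(lay$w) - 1) > 1e-12) stop("layer ", l, ": weights must sum to 1")
    if (any(lay$w <= 0) || length(lay$w) != K) stop("layer ", l, ": invalid weights")
    if (!all(dim(lay$mu) == c(p, K))) stop("layer ", l, ": mu must be ", p, " x ", K)
    if (!all(dim(lay$delta) == c(p, K)) || any(lay$delta <= 0))
      stop("layer ", l, ": delta must be positive, ", p, " x ", K)
    if (length(lay$B) != K) stop("layer ", l, ": need one loading per component")
    for (k in seq_len(K)) {
      Bk <- lay$B[[k]]
      if (!all(dim(Bk) == c(p, q))) stop("layer ", l, " component ", k, ": loading must be ", p, " x ", q)
      for (j in seq_len(p)) {
        if (q > j && any(Bk[j, (j + 1L):q] != 0))
          stop("layer ", l, " component ", k, ": loading must be lower triangular")
      }
    }
  }
  structure(list(arch = arch, layers = layers), class = "DMFAParameters")
}

#' Sample random effects from the DMFA prior
#'
#' @param params a DMFAParameters object.
#' @param n number of draws.
#' @param seed integer seed (optional; NULL leaves the RNG state alone).
#' @return list with \code{z} (n x d matrix of draws) and \code{paths}
#'   (n x L matrix of per-layer component choices).
#' @export
sampleRandomEffects <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- params$arch
  L <- length(arch@K)
  DL <- arch@D[L + 1L]
  Z <- matrix(stats::rnorm(n * DL), n, DL)
  paths <- matrix(0L, n, L)
  for (l in L:1) {
    lay <- params$layers[[l]]
    p <- arch@D[l]
    k <- sample.int(arch@K[l], n, replace = TRUE, prob = lay$w)
    paths[, l] <- k
    Znew <- matrix(0, n, p)
    for (kk in seq_len(arch@K[l])) {
      idx <- which(k == kk)
      if (!length(idx)) next
      eps <- matrix(stats::rnorm(length(idx) * p), length(idx), p) *
        rep(sqrt(lay$delta[, kk]), each = length(idx))
      Znew[idx, ] <- Z[idx, , drop = FALSE] %*% t(lay$B[[kk]]) +
        rep(lay$mu[, kk], each = length(idx)) + eps
    }
    Z <- Znew
  }
  list(z = Z, paths = paths)
}

## Enumerate all paths lexicographically in (k_1, ..., k_L).
enumeratePaths <- function(K) {
  L <- length(K)
  grid <- as.matrix(expand.grid(rev(lapply(K, seq_len)), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, L:1, drop = FALSE]
  colnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  grid
}

#' Collapse the layered prior to an explicit Gaussian mixture
#'
#' Enumerates the K = prod(K_l) paths. For path k = (k_1, ..., k_L) with
#' cumulative loading products A_l = B(1) ... B(l):
#' weight prod_l w_{k_l}; mean sum_l A_{l-1} mu(l); covariance
#' sum_l A_{l-1} delta(l) A_{l-1}' + A_L A_L' (the final term carries the
#' N(0, I) top-layer variance).
#'
#' @param params a DMFAParameters object.
#' @return a \linkS4class{GaussianMixture} with path labels in lexicographic
#'   order.
#' @export
collapseToGMM <- function(params) {
  arch <- params$arch
  L <- length(arch@K)
  d <- arch@D[1L]
  paths <- enumeratePaths(arch@K)
  Ktot <- nrow(paths)
  w <- numeric(Ktot)
  means <- matrix(0, d, Ktot)
  covs <- array(0, c(d, d, Ktot))
  for (k in seq_len(Ktot)) {
    A <- diag(1, d)
    mu <- numeric(d)
    S <- matrix(0, d, d)
    wk <- 1
    for (l in seq_len(L)) {
      lay <- params$layers[[l]]
      kl <- paths[k, l]
      wk <- wk * lay$w[kl]
      mu <- mu + A %*% lay$mu[, kl]
      S <- S + A %*% (lay$delta[, kl] * t(A))
      A <- A %*% lay$B[[kl]]
    }
    S <- S + tcrossprod(A)
    w[k] <- wk
    means[, k] <- mu
    covs[, , k] <- (S + t(S)) / 2
  }
  new("GaussianMixture", weights = w / sum(w), means = means, covariances = covs,
      pathLabels = paths)
}
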