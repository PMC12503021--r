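## Shared fixtures: random mixture/parameter generators and small utilities.
## Everything is built in code at test time; no stored data.

## Random symmetric positive-definite matrix.
rspd <- function(d, scale = 1) {
  A <- matrix(stats::rnorm(d * d), d, d)
  scale * (crossprod(A) / d + diag(0.1, d))
}

## Random GaussianMixture of dimension d with K components.
randomGMM <- function(d, K, mean_scale = 2) {
  w <- as.numeric(prop.table(stats::runif(K) + 0.2))
  means <- matrix(stats::rnorm(d * K, 0, mean_scale), d, K)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) covs[, , k] <- rspd(d)
  gaussianMixture(w, means, covs)
}

## Random valid DMFAParameters for a given architecture.
randomDMFAParams <- function(arch, loading_sd = 0.5) {
  L <- length(arch@K)
  layers <- lapply(seq_len(L), function(l) {
    p <- arch@D[l]; q <- arch@D[l + 1L]; K <- arch@K[l]
    B <- lapply(seq_len(K), function(k) {
      M <- matrix(stats::rnorm(p * q, 0, loading_sd), p, q)
      M[!dmlmm:::lowerTriMask(p, q)] <- 0
      M
    })
    list(w = as.numeric(prop.table(stats::runif(K) + 0.5)),
         mu = matrix(stats::rnorm(p * K), p, K),
         B = B,
         delta = matrix(stats::runif(p * K, 0.1, 0.5), p, K))
  })
  dmfaParameters(arch, layers)
}

## Well-separated two-component mixture-of-factor-analyzers truth in d = 6,
## used by the parameter-recovery experiments.
recoveryTruth <- function() {
  d <- 6L
  B1 <- matrix(0, d, 2)
  B1[, 1] <- c(1, 0.7, 0.5, 0.3, 0.2, 0.1)
  B1[2:6, 2] <- c(0.6, -0.4, 0.5, -0.2, 0.1)
  B1[!dmlmm:::lowerTriMask(d, 2)] <- 0
  mu1 <- c(3, 1.5, 0, 1, 0, 0)
  S1 <- tcrossprod(B1) + diag(0.15, d)
  gaussianMixture(c(0.5, 0.5), cbind(mu1, -mu1), array(c(S1, S1), c(d, d, 2)))
}

## Balanced-design sample from the recovery truth: every subject observed on
## the same equispaced grid.
recoverySample <- function(n, seed, ni = 25L, noise_sd = 0.2,
                           basis = legendreBasis(6L, c(0, 1))) {
  set.seed(seed)
  truth <- recoveryTruth()
  tgrid <- seq(0, 1, length.out = ni)
  B <- designMatrix(basis, tgrid)
  dr <- sampleGMM(truth, n)
  vals <- lapply(seq_len(n), function(i)
    as.numeric(B %*% dr$x[i, ]) + stats::rnorm(ni, 0, noise_sd))
  list(data = longitudinalData(sprintf("s%04d", seq_len(n)),
                               rep(list(tgrid), n), vals),
       labels = dr$component, beta = dr$x, truth = truth,
       sigma2 = noise_sd^2, basis = basis, tgrid = tgrid)
}

## Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  e <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  (sc(as.vector(tab)) - e) / (0.5 * (sc(rowSums(tab)) + sc(colSums(tab))) - e)
}

## Small toy dataset from a 2-component coefficient mixture (d = 4).
toyData <- function(n = 30, ni = 6, seed = 4) {
  basis <- legendreBasis(4, c(0, 1))
  means <- cbind(c(2, 1, 0, 0), c(-2, -1, 0, 0))
  covs <- array(0, c(4, 4, 2))
  covs[, , 1] <- diag(0.2, 4); covs[, , 2] <- diag(0.2, 4)
  truth <- gaussianMixture(c(0.5, 0.5), means, covs)
  dg <- generateFromDMLMM(truth, sigma2 = 0.09, basis = basis,
                          n_subjects = n, ni = ni, seed = seed)
  list(dg = dg, basis = basis, truth = truth)
}

## Inverse-gamma sampler (shape-rate).
rinvgamma <- function(n, a, b) 1 / stats::rgamma(n, shape = a, rate = b)
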