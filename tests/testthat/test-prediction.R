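## A fitted-model stand-in built directly from a mixture: prediction operates
## only on the collapsed representation, so fits are not needed here.
mixtureFit <- function(gmm, sigma2, basis) {
  new("DMLMMFit", gmm = gmm, sigma2 = sigma2, basis = basis,
      architecture = dmfaArchitecture(c(max(basis@d, 3), 1), length(gmm@weights)),
      elboTrace = matrix(numeric(0), 0, 2),
      responsibilities = matrix(numeric(0), 0, length(gmm@weights)), seed = 1L)
}

test_that("conditioning on nothing returns the prior-projected mixture", {
  set.seed(41)
  basis <- legendreBasis(3, c(0, 1))
  gmm <- randomGMM(3, 2)
  fit <- mixtureFit(gmm, 0.3, basis)
  tq <- c(0.2, 0.8)
  Bt <- designMatrix(basis, tq)
  pred <- marginalPredictive(fit, tq)
  expect_equal(pred@weights, gmm@weights)
  for (k in 1:2) {
    expect_equal(pred@means[, k], as.numeric(Bt %*% gmm@means[, k]))
    expect_equal(pred@covariances[, , k],
                 Bt %*% gmm@covariances[, , k] %*% t(Bt) + diag(0.3, 2))
  }
  ## mean function and variance floor
  mo <- predictiveMoments(pred)
  expect_equal(mo$mean, as.numeric((Bt %*% gmm@means) %*% gmm@weights))
  expect_true(all(mo$variance >= 0.3))
})

test_that("near-noiseless conditioning interpolates the observations", {
  set.seed(43)
  basis <- legendreBasis(3, c(0, 1))
  gmm <- randomGMM(3, 1)
  fit <- mixtureFit(gmm, 1e-10, basis)
  t_i <- c(0.2, 0.5, 0.9)
  y_i <- c(0.4, -0.3, 1.1)
  pred <- conditionalPredictive(fit, y_i, t_i, t_i)
  expect_lt(max(abs(as.numeric(pred@means %*% pred@weights) - y_i)), 1e-3)
})

test_that("conditional predictive equals the brute-force joint conditional", {
  set.seed(47)
  for (r in 1:10) {
    d <- sample(2:4, 1); ni <- sample(1:3, 1); TT <- sample(1:2, 1)
    K <- sample(1:3, 1)
    basis <- legendreBasis(d, c(0, 1))
    gmm <- randomGMM(d, K)
    s2 <- runif(1, 0.05, 0.5)
    fit <- mixtureFit(gmm, s2, basis)
    t_i <- runif(ni); y_i <- rnorm(ni); tq <- runif(TT)
    pred <- conditionalPredictive(fit, y_i, t_i, tq)
    Ball <- designMatrix(basis, c(t_i, tq))
    jm <- Ball %*% gmm@means
    jc <- array(0, c(ni + TT, ni + TT, K))
    for (k in seq_len(K))
      jc[, , k] <- Ball %*% gmm@covariances[, , k] %*% t(Ball) + diag(s2, ni + TT)
    joint <- gaussianMixture(gmm@weights, matrix(jm, ni + TT, K), jc)
    margi <- gaussianMixture(gmm@weights, matrix(jm[1:ni, ], ni, K),
                             array(jc[1:ni, 1:ni, ], c(ni, ni, K)))
    probes <- matrix(rnorm(20 * TT), 20, TT)
    direct <- gmmLogpdf(joint, cbind(matrix(y_i, 20, ni, byrow = TRUE), probes)) -
      as.numeric(gmmLogpdf(margi, y_i))
    ours <- gmmLogpdf(dmlmm:::asGaussianMixture(pred), probes)
    expect_equal(ours, direct, tolerance = 1e-8)
  }
})

test_that("sequential conditioning equals joint conditioning (tower property)", {
  set.seed(53)
  basis <- legendreBasis(4, c(0, 1))
  gmm <- randomGMM(4, 2)
  fit <- mixtureFit(gmm, 0.2, basis)
  t1 <- c(0.1, 0.4); y1 <- c(0.5, -0.1)
  t2 <- c(0.6, 0.85); y2 <- c(0.2, 0.9)
  tq <- c(0.3, 0.7)
  all_at_once <- conditionalPredictive(fit, c(y1, y2), c(t1, t2), tq)
  ## two-stage: first the joint predictive of (y2, yq) given y1, then a manual
  ## Gaussian conditioning of that mixture on y2. Conditioning twice must equal
  ## conditioning on the union.
  joint12 <- conditionalPredictive(fit, y1, t1, c(t2, tq))
  K <- length(joint12@weights)
  lw <- numeric(K); m2 <- matrix(0, 2, K); c2 <- array(0, c(2, 2, K))
  for (k in seq_len(K)) {
    S <- joint12@covariances[, , k]; m <- joint12@means[, k]
    A <- S[3:4, 1:2] %*% solve(S[1:2, 1:2])
    lw[k] <- log(joint12@weights[k]) +
      dmlmm:::mvnLogpdf(y2, m[1:2], S[1:2, 1:2])
    m2[, k] <- m[3:4] + A %*% (y2 - m[1:2])
    c2[, , k] <- S[3:4, 3:4] - A %*% S[1:2, 3:4]
  }
  stage <- gaussianMixture(exp(lw - dmlmm:::logSumExp(lw)), m2, c2)
  probes <- matrix(rnorm(20), 10, 2)
  expect_equal(gmmLogpdf(stage, probes),
               gmmLogpdf(dmlmm:::asGaussianMixture(all_at_once), probes),
               tolerance = 1e-8)
  ## predictive weights are normalized and covariances PD
  expect_equal(sum(all_at_once@weights), 1, tolerance = 1e-10)
  for (k in 1:2)
    expect_gt(min(eigen(all_at_once@covariances[, , k],
                        symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("threshold risk is a proper scalar mixture CDF", {
  set.seed(59)
  basis <- legendreBasis(3, c(0, 1))
  gmm <- randomGMM(3, 2)
  fit <- mixtureFit(gmm, 0.3, basis)
  pred <- marginalPredictive(fit, c(0.25, 0.75))
  expect_equal(thresholdRisk(pred, 1, -1e9), 0, tolerance = 1e-12)
  expect_equal(thresholdRisk(pred, 1, 1e9), 1, tolerance = 1e-12)
  ## single symmetric component at its mean
  g1 <- gaussianMixture(1, matrix(c(0.5, 0, 0), 3, 1),
                        array(diag(0.2, 3), c(3, 3, 1)))
  p1 <- marginalPredictive(mixtureFit(g1, 0.1, basis), 0.5)
  expect_equal(thresholdRisk(p1, 1, p1@means[1, 1]), 0.5)
  ## Monte-Carlo frequency oracle
  draws <- sampleGMM(dmlmm:::asGaussianMixture(pred), 2e5, seed = 60)$x
  cc <- 0.4
  mc <- mean(draws[, 2] <= cc)
  se <- sqrt(mc * (1 - mc) / 2e5)
  expect_lt(abs(thresholdRisk(pred, 2, cc) - mc), 3 * se + 1e-6)
})

test_that("pointwise intervals invert the mixture CDF", {
  basis <- legendreBasis(3, c(0, 1))
  g1 <- gaussianMixture(1, matrix(c(1, 0.5, 0), 3, 1),
                        array(diag(0.3, 3), c(3, 3, 1)))
  fit <- mixtureFit(g1, 0.2, basis)
  pred <- marginalPredictive(fit, c(0.3, 0.6))
  ci <- pointwiseInterval(pred, 0.95)
  mo <- predictiveMoments(pred)
  for (j in 1:2) {
    expect_equal(unname(ci[j, 1]), mo$mean[j] - 1.959964 * sqrt(mo$variance[j]),
                 tolerance = 1e-6)
    expect_equal(unname(ci[j, 2]), mo$mean[j] + 1.959964 * sqrt(mo$variance[j]),
                 tolerance = 1e-6)
  }
  ## nestedness in the level
  set.seed(61)
  gmix <- randomGMM(3, 2)
  predm <- marginalPredictive(mixtureFit(gmix, 0.3, basis), c(0.2, 0.9))
  ci50 <- pointwiseInterval(predm, 0.5)
  ci95 <- pointwiseInterval(predm, 0.95)
  expect_true(all(ci95[, 1] < ci50[, 1]))
  expect_true(all(ci95[, 2] > ci50[, 2]))
  ## self-consistency: draws from the predictive fall inside at ~ the level
  draws <- sampleGMM(dmlmm:::asGaussianMixture(predm), 2000, seed = 62)$x
  cover <- mean(draws[, 1] >= ci95[1, 1] & draws[, 1] <= ci95[1, 2])
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 2000))
})

test_that("elliptical credible sets are calibrated for Gaussian truth", {
  set.seed(67)
  basis <- legendreBasis(3, c(0, 1))
  g1 <- gaussianMixture(1, matrix(rnorm(3), 3, 1), array(rspd(3), c(3, 3, 1)))
  fit <- mixtureFit(g1, 0.2, basis)
  tq <- c(0.2, 0.5, 0.8)
  pred <- marginalPredictive(fit, tq)
  truth <- sampleGMM(dmlmm:::asGaussianMixture(pred), 4000, seed = 68)$x
  cov95 <- ellipticalSetCoverage(pred, 0.95, truth)
  expect_lt(abs(cov95 - 0.95), 3 * sqrt(0.95 * 0.05 / 4000))
  expect_equal(ellipticalSetCoverage(pred, 0, truth), 0)
  ## the moment-matched ellipsoid is biased for a separated bimodal mixture:
  ## at low levels the central ellipsoid contains neither mode, so it
  ## undercovers badly there (and overcovers at high levels)
  far <- gaussianMixture(c(0.5, 0.5), cbind(c(5, 0, 0), c(-5, 0, 0)),
                         array(c(diag(0.1, 3), diag(0.1, 3)), c(3, 3, 2)))
  pf <- marginalPredictive(mixtureFit(far, 0.05, basis), tq)
  tf <- sampleGMM(dmlmm:::asGaussianMixture(pf), 4000, seed = 69)$x
  expect_lt(ellipticalSetCoverage(pf, 0.2, tf), 0.1)
  expect_gt(ellipticalSetCoverage(pf, 0.95, tf), 0.95)
})

test_that("cluster assignment follows the posterior path probabilities", {
  basis <- legendreBasis(3, c(0, 1))
  set.seed(71)
  ## single component: everyone gets label 1 with probability 1
  g1 <- randomGMM(3, 1)
  fit1 <- mixtureFit(g1, 0.2, basis)
  dat <- generateFromDMLMM(g1, 0.2, basis, n_subjects = 5, ni = 4, seed = 72)
  cl1 <- clusterAssign(fit1, dat$data)
  expect_true(all(cl1$label == 1L))
  expect_equal(cl1$probability, matrix(1, 5, 1))
  ## symmetric components and equidistant data: probabilities (1/2, 1/2)
  S <- diag(0.5, 3)
  gsym <- gaussianMixture(c(0.5, 0.5), cbind(c(2, 0, 0), c(-2, 0, 0)),
                          array(c(S, S), c(3, 3, 2)))
  fit2 <- mixtureFit(gsym, 0.1, basis)
  tt <- c(0.2, 0.5, 0.8)
  y0 <- rep(0, 3)   # equidistant from both component projections
  cl2 <- clusterAssign(fit2, longitudinalData("a", list(tt), list(y0)))
  expect_equal(as.numeric(cl2$probability), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(cl2$label, 1L)  # tie broken toward the lowest index
})

test_that("conflict statistic matches the closed-form Gaussian KL for K = 1", {
  set.seed(73)
  basis <- legendreBasis(3, c(0, 1))
  g1 <- gaussianMixture(1, matrix(c(0.5, -1, 0.3), 3, 1),
                        array(rspd(3), c(3, 3, 1)))
  fit <- mixtureFit(g1, 0.2, basis)
  t_past <- c(0.1, 0.3); t_fut <- c(0.6, 0.9)
  y_past <- c(0.8, 0.2)
  res <- conflictPvalue(fit, y_past, t_past, t_fut, n_sim = 30, n_kl = 4000,
                        seed = 74)
  cond <- dmlmm:::asGaussianMixture(conditionalPredictive(fit, y_past, t_past, t_fut))
  marg <- dmlmm:::asGaussianMixture(marginalPredictive(fit, t_fut))
  S0 <- marg@covariances[, , 1]; S1 <- cond@covariances[, , 1]
  dm <- marg@means[, 1] - cond@means[, 1]
  kl <- 0.5 * (sum(diag(solve(S0, S1))) + sum(dm * solve(S0, dm)) - 2 +
                 determinant(S0)$modulus[1] - determinant(S1)$modulus[1])
  expect_lt(abs(res$G_obs - kl), 3 * res$G_obs_se)
  ## independent segments: zero divergence, p near 1
  gd <- gaussianMixture(1, matrix(0, 3, 1), array(diag(1e-12, 3), c(3, 3, 1)))
  fitd <- mixtureFit(gd, 0.3, basis)
  resd <- conflictPvalue(fitd, c(0.1, -0.2), t_past, t_fut, n_sim = 30,
                         n_kl = 1000, seed = 75)
  expect_lt(abs(resd$G_obs), 1e-6)
  expect_gt(resd$p, 0.5)
  expect_warning(conflictPvalue(fit, y_past, t_past, t_fut, n_sim = 5,
                                n_kl = 100, seed = 76), "coarse")
  expect_error(conflictPvalue(fit, numeric(0), numeric(0), t_fut), "nonempty")
})

test_that("metrics follow their closed forms and guard degenerate cases", {
  m0 <- predictionMetrics(list(c(1, 2), 3), list(c(1, 2), 3))
  expect_equal(m0$mean_rmse, 0)
  expect_true(m0$degenerate)
  expect_true(is.na(m0$log_rmse))
  mc <- predictionMetrics(list(c(1, 2, 3) + 0.5), list(c(1, 2, 3)))
  expect_equal(mc$rmse, 0.5)
  expect_equal(mc$log_rmse, log(0.5))
  ms <- predictionMetrics(list(0), list(0), logdens = dnorm(0, log = TRUE))
  expect_equal(ms$neg_log_score, 0.9189385, tolerance = 1e-6)
  expect_error(predictionMetrics(list(), list()), "empty held-out")
  expect_error(predictionMetrics(list(numeric(0)), list(numeric(0))),
               "empty held-out")
})
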