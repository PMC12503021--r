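cloneState <- function(st) {
  st2 <- new.env(parent = emptyenv())
  for (nm in ls(st)) assign(nm, get(nm, envir = st), envir = st2)
  st2
}

test_that("initialization is deterministic and robust to tiny subjects", {
  td <- toyData()
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  arch <- dmfaArchitecture(c(4, 1), 2)
  ctrl <- dmlmmControl(seed = 5)
  s1 <- dmlmm:::initState(cache, arch, dmlmmPrior(), ctrl)
  s2 <- dmlmm:::initState(cache, arch, dmlmmPrior(), ctrl)
  expect_identical(s1$loc$beta_m, s2$loc$beta_m)
  expect_identical(s1$g$layers[[1]]$mu_m, s2$g$layers[[1]]$mu_m)
  expect_identical(s1$loc$r[[1]], s2$loc$r[[1]])
  ## a subject with a single observation must not break the ridge init
  one <- longitudinalData(c("a", "b", "c"),
                          list(0.5, c(0.1, 0.9), c(0.2, 0.4, 0.8)),
                          list(1.0, c(0.5, -0.5), c(1, 0, -1)))
  cache1 <- dmlmm:::buildDataCache(one, legendreBasis(4, c(0, 1)))
  s3 <- dmlmm:::initState(cache1, arch, dmlmmPrior(), ctrl)
  expect_true(all(is.finite(s3$loc$beta_m)))
})

test_that("initial partition recovers well-separated clusters", {
  rs <- recoverySample(150, seed = 77, ni = 12)
  cache <- dmlmm:::buildDataCache(rs$data, rs$basis)
  st <- dmlmm:::initState(cache, dmfaArchitecture(c(6, 2), 2), dmlmmPrior(),
                          dmlmmControl(seed = 1))
  expect_gt(adjustedRand(max.col(st$loc$r[[1]]), rs$labels), 0.9)
})

test_that("local coordinate ascent is monotone for every subject", {
  td <- toyData(n = 12)
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  st <- dmlmm:::initState(cache, dmfaArchitecture(c(4, 1), 2), dmlmmPrior(),
                          dmlmmControl(seed = 2))
  objs <- dmlmm:::updateLocalsBatch(st, cache, 1:12, n_inner = 6,
                                    inner_tol = 0, trace = TRUE)
  expect_gte(nrow(objs), 2)
  incr <- apply(objs, 2, diff)
  expect_true(all(incr > -1e-8))
})

test_that("q(beta) update matches the conjugate-normal closed form", {
  td <- toyData(n = 8)
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  st <- dmlmm:::initState(cache, dmfaArchitecture(c(4, 1), 1), dmlmmPrior(),
                          dmlmmControl(seed = 3))
  ## single component, loadings forced to zero, factor scores to zero
  st$g$layers[[1]]$B_m[[1]][] <- 0
  st$g$layers[[1]]$B_S[[1]] <- lapply(1:4, function(j) diag(1e-12, 1))
  dmlmm:::refreshLayerCache(st, 1)
  st$loc$z_m[[1]][] <- 0
  dmlmm:::updateBeta(st, cache, 1:8)
  gl <- st$g$layers[[1]]
  E1d <- gl$delta_a[1] / gl$delta_b[, 1]
  for (i in 1:8) {
    P <- st$Es2inv * cache$BtB[, , i] + diag(E1d)
    h <- st$Es2inv * cache$Bty[, i] + E1d * gl$mu_m[, 1]
    expect_equal(st$loc$beta_m[i, ], as.numeric(solve(P, h)), tolerance = 1e-8)
    expect_equal(st$loc$beta_v[i, ], 1 / diag(P), tolerance = 1e-10)
  }
})

test_that("a subject with no observations gets the prior-implied factor", {
  td <- toyData(n = 6)
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  ## append a pseudo-subject with n_i = 0
  cache$B <- c(cache$B, list(matrix(0, 0, 4)))
  cache$BtB <- array(c(cache$BtB, matrix(0, 4, 4)), c(4, 4, 7))
  cache$Bty <- cbind(cache$Bty, 0)
  cache$yty <- c(cache$yty, 0)
  cache$ni <- c(cache$ni, 0L)
  ## cache$n is still 6, so initialization runs on the real subjects only
  st <- dmlmm:::initState(cache, dmfaArchitecture(c(4, 1), 1), dmlmmPrior(),
                          dmlmmControl(seed = 4))
  ## extend locals to the pseudo-subject
  st$n <- 7L
  st$loc$beta_m <- rbind(st$loc$beta_m, 0)
  st$loc$beta_v <- rbind(st$loc$beta_v, 1)
  st$loc$z_m[[1]] <- rbind(st$loc$z_m[[1]], 0)
  st$loc$z_v[[1]] <- rbind(st$loc$z_v[[1]], 1)
  st$loc$r[[1]] <- rbind(st$loc$r[[1]], 1)
  dmlmm:::updateBeta(st, cache, 7L)
  gl <- st$g$layers[[1]]
  E1d <- gl$delta_a[1] / gl$delta_b[, 1]
  pred <- gl$mu_m[, 1] + as.numeric(gl$B_m[[1]] %*% st$loc$z_m[[1]][7, ])
  expect_equal(st$loc$beta_m[7, ], pred, tolerance = 1e-10)
  expect_equal(st$loc$beta_v[7, ], 1 / E1d, tolerance = 1e-10)
})

test_that("full-batch unit steps keep the full-data ELBO non-decreasing", {
  td <- toyData(n = 20)
  fit <- fitDMLMM(td$dg$data, dmfaArchitecture(c(4, 1), 2), basis = td$basis,
                  control = dmlmmControl(iterations = 40, minibatch = 100,
                                         elbo_every = 1, seed = 6))
  tr <- fit@elboTrace[, 2]
  expect_true(all(diff(tr) > -1e-6))
  expect_gt(tr[length(tr)], tr[1])
})

test_that("minibatch natural-parameter targets are unbiased by enumeration", {
  td <- toyData(n = 4, ni = 5, seed = 9)
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  st <- dmlmm:::initState(cache, dmfaArchitecture(c(4, 1), 2), dmlmmPrior(),
                          dmlmmControl(seed = 7))
  dmlmm:::updateLocalsBatch(st, cache, 1:4)
  full <- cloneState(st)
  dmlmm:::globalStep(full, cache, 1:4, 1)
  acc_dir <- 0; acc_s2 <- c(0, 0)
  for (i in 1:4) {
    sti <- cloneState(st)
    dmlmm:::globalStep(sti, cache, i, 1)
    acc_dir <- acc_dir + sti$g$layers[[1]]$dirichlet / 4
    acc_s2 <- acc_s2 + unname(sti$g$sigma2) / 4
  }
  expect_equal(acc_dir, full$g$layers[[1]]$dirichlet, tolerance = 1e-10)
  expect_equal(acc_s2, unname(full$g$sigma2), tolerance = 1e-10)
  ## minibatch of the full data equals the deterministic update
  full2 <- cloneState(st)
  dmlmm:::globalStep(full2, cache, c(3, 1, 4, 2), 1)
  expect_equal(full2$g$sigma2, full$g$sigma2, tolerance = 1e-12)
})

test_that("closed-form ELBO matches a Monte-Carlo estimate", {
  td <- toyData(n = 3, ni = 4, seed = 12)
  cache <- dmlmm:::buildDataCache(td$dg$data, td$basis)
  arch <- dmfaArchitecture(c(4, 1), 2)
  hp <- dmlmmPrior()
  st <- dmlmm:::initState(cache, arch, hp, dmlmmControl(seed = 8))
  for (m in 1:5) {
    dmlmm:::updateLocalsBatch(st, cache, 1:3)
    dmlmm:::naturalGradientGlobalStep(st, cache, 1:3, 1)
  }
  dmlmm:::updateLocalsBatch(st, cache, 1:3)
  closed <- dmlmm:::elboState(st, cache)$total
  gl <- st$g$layers[[1]]
  p <- 4; q <- 1; K <- 2
  mask <- dmlmm:::lowerTriMask(p, q)
  set.seed(99)
  nmc <- 4000
  vals <- vapply(seq_len(nmc), function(s) {
    lq <- 0
    ## globals
    s2 <- rinvgamma(1, st$g$sigma2[["a"]], st$g$sigma2[["b"]])
    lq <- lq + dmlmm:::igLogpdf(s2, st$g$sigma2[["a"]], st$g$sigma2[["b"]])
    psi <- rinvgamma(1, st$g$psi[["a"]], st$g$psi[["b"]])
    lq <- lq + dmlmm:::igLogpdf(psi, st$g$psi[["a"]], st$g$psi[["b"]])
    gw <- rgamma(K, gl$dirichlet, 1); w <- gw / sum(gw)
    lq <- lq + sum((gl$dirichlet - 1) * log(w)) + dmlmm:::dirichletLogC(gl$dirichlet)
    mu <- matrix(rnorm(p * K, gl$mu_m, sqrt(gl$mu_v)), p, K)
    lq <- lq + sum(dnorm(mu, gl$mu_m, sqrt(gl$mu_v), log = TRUE))
    delta <- matrix(0, p, K); B <- list(); tau_mu <- matrix(0, p, K)
    a_delta <- matrix(0, p, K); lam <- list(); nu <- list()
    for (k in 1:K) {
      delta[, k] <- rinvgamma(p, gl$delta_a[k], gl$delta_b[, k])
      lq <- lq + sum(dmlmm:::igLogpdf(delta[, k], gl$delta_a[k], gl$delta_b[, k]))
      a_delta[, k] <- rinvgamma(p, 1, gl$a_delta_b[, k])
      lq <- lq + sum(dmlmm:::igLogpdf(a_delta[, k], 1, gl$a_delta_b[, k]))
      tau_mu[, k] <- rinvgamma(p, 1, gl$tau_mu_b[, k])
      lq <- lq + sum(dmlmm:::igLogpdf(tau_mu[, k], 1, gl$tau_mu_b[, k]))
      Bk <- matrix(0, p, q)
      for (j in 1:p) {
        f <- min(j, q); sf <- seq_len(f)
        S <- gl$B_S[[k]][[j]]
        draw <- as.numeric(gl$B_m[[k]][j, sf] + t(chol(S)) %*% rnorm(f))
        Bk[j, sf] <- draw
        lq <- lq + dmlmm:::mvnLogpdf(draw, gl$B_m[[k]][j, sf], S)
      }
      B[[k]] <- Bk
      lamk <- matrix(1, p, q); nuk <- matrix(1, p, q)
      lamk[mask] <- rinvgamma(sum(mask), 1, gl$lam_b[[k]][mask])
      nuk[mask] <- rinvgamma(sum(mask), 1, gl$nu_b[[k]][mask])
      lq <- lq + sum(dmlmm:::igLogpdf(lamk[mask], 1, gl$lam_b[[k]][mask])) +
        sum(dmlmm:::igLogpdf(nuk[mask], 1, gl$nu_b[[k]][mask]))
      lam[[k]] <- lamk; nu[[k]] <- nuk
    }
    tau2 <- rinvgamma(1, gl$tau2[["a"]], gl$tau2[["b"]])
    lq <- lq + dmlmm:::igLogpdf(tau2, gl$tau2[["a"]], gl$tau2[["b"]])
    xi <- rinvgamma(1, 1, gl$xi_b)
    lq <- lq + dmlmm:::igLogpdf(xi, 1, gl$xi_b)
    ## locals
    lh <- 0
    for (i in 1:3) {
      beta <- rnorm(p, st$loc$beta_m[i, ], sqrt(st$loc$beta_v[i, ]))
      lq <- lq + sum(dnorm(beta, st$loc$beta_m[i, ], sqrt(st$loc$beta_v[i, ]),
                           log = TRUE))
      z <- rnorm(q, st$loc$z_m[[1]][i, ], sqrt(st$loc$z_v[[1]][i, ]))
      lq <- lq + sum(dnorm(z, st$loc$z_m[[1]][i, ], sqrt(st$loc$z_v[[1]][i, ]),
                           log = TRUE))
      si <- sample.int(K, 1, prob = st$loc$r[[1]][i, ])
      lq <- lq + log(st$loc$r[[1]][i, si])
      lh <- lh + completeDataLoglik(cache$y[[i]], cache$B[[i]], beta, s2) +
        log(w[si]) +
        sum(dnorm(beta, mu[, si] + as.numeric(B[[si]] %*% z), sqrt(delta[, si]),
                  log = TRUE)) +
        sum(dnorm(z, log = TRUE))
    }
    params <- dmfaParameters(arch, list(list(w = w, mu = mu, B = B,
                                             delta = delta)))
    aux <- list(list(tau_mu = tau_mu, a_delta = a_delta, lambda2 = lam,
                     nu = nu, tau2 = tau2, xi = xi))
    lh <- lh + logPriorSigma(s2, psi, hp$A) + logPriorDMFA(params, aux, hp)
    lh - lq
  }, numeric(1))
  se <- sd(vals) / sqrt(nmc)
  expect_lt(abs(mean(vals) - closed), 3 * se)
})

test_that("pruning zeroes argmax-empty components and rescales", {
  g <- randomGMM(2, 4)
  r <- matrix(0.01, 5, 4); r[, 1] <- 0.97
  pruned <- pruneEmptyComponents(g, r)
  expect_equal(pruned@weights, c(1, 0, 0, 0))
  ## no empty components: unchanged
  r2 <- diag(4)[c(1, 2, 3, 4), ]
  expect_equal(pruneEmptyComponents(g, r2)@weights, g@weights)
  ## argmax counts (5, 0, 3)
  g3 <- randomGMM(2, 3)
  r3 <- rbind(matrix(rep(c(0.8, 0.1, 0.1), 5), 5, 3, byrow = TRUE),
              matrix(rep(c(0.1, 0.1, 0.8), 3), 3, 3, byrow = TRUE))
  p3 <- pruneEmptyComponents(g3, r3)
  expect_equal(p3@weights,
               c(g3@weights[1], 0, g3@weights[3]) /
                 (g3@weights[1] + g3@weights[3]))
})

test_that("fits are deterministic given the seed", {
  td <- toyData(n = 15)
  ctrl <- dmlmmControl(iterations = 15, seed = 11)
  f1 <- fitDMLMM(td$dg$data, dmfaArchitecture(c(4, 1), 2), basis = td$basis,
                 control = ctrl)
  f2 <- fitDMLMM(td$dg$data, dmfaArchitecture(c(4, 1), 2), basis = td$basis,
                 control = ctrl)
  expect_identical(f1@elboTrace, f2@elboTrace)
  expect_identical(f1@gmm@weights, f2@gmm@weights)
  expect_identical(f1@sigma2, f2@sigma2)
})

test_that("architecture selection ranks by short-run ELBO with sane ties", {
  td <- toyData(n = 40, seed = 21)
  a1 <- dmfaArchitecture(c(4, 1), 1)
  a2 <- dmfaArchitecture(c(4, 1), 2)
  one <- selectArchitecture(td$dg$data, list(a2), short_iters = 10,
                            basis = td$basis, control = dmlmmControl(seed = 1))
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$elbo))
  ## identical candidates tie and keep input order
  two <- selectArchitecture(td$dg$data, list(a2, a2), short_iters = 10,
                            basis = td$basis, control = dmlmmControl(seed = 1))
  expect_equal(two$elbo[1], two$elbo[2])
  expect_equal(two$candidate, c(1L, 2L))
  expect_error(selectArchitecture(td$dg$data, list()), "empty candidate")
  ## on two-cluster data the K = 2 candidate outranks K = 1 in most runs
  wins <- 0
  for (s in 1:5) {
    tds <- toyData(n = 40, seed = 30 + s)
    rk <- selectArchitecture(tds$dg$data, list(a1, a2), short_iters = 25,
                             basis = tds$basis,
                             control = dmlmmControl(seed = s, minibatch = 100))
    wins <- wins + (rk$candidate[1] == 2L)
  }
  expect_gte(wins, 4)
})
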