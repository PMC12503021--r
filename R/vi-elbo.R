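## Closed-form evidence lower bound, decomposed as L = L_DMFA + L_Reg.
## Every expectation is analytic under the Gaussian / inverse-gamma /
## Dirichlet / categorical factors; agreement with a Monte-Carlo estimate of
## E_q[log h(theta) - log q(theta)] is exercised in the tests.

elboState <- function(st, cache) {
  n <- st$n
  idx <- seq_len(n)
  lg <- lgamma(0.5)

  ## ---- regression part ----
  MB <- st$loc$beta_m; VB <- st$loc$beta_v
  qf <- 0
  for (i in idx) {
    b <- MB[i, ]
    qf <- qf + cache$yty[i] - 2 * sum(cache$Bty[, i] * b) +
      sum(b * (cache$BtB[, , i] %*% b)) + sum(diag(cache$BtB[, , i]) * VB[i, ])
  }
  reg <- -0.5 * cache$Ntot * (log(2 * pi) + st$Elogs2) - 0.5 * st$Es2inv * qf
  reg <- reg + (-0.5 * st$Elogpsi - lg - 1.5 * st$Elogs2 - st$E1psi * st$Es2inv)
  reg <- reg + (log(1 / st$prior$A^2) / 2 - lg - 1.5 * st$Elogpsi -
                  st$E1psi / st$prior$A^2)
  reg <- reg + igEntropy(st$g$sigma2[["a"]], st$g$sigma2[["b"]]) +
    igEntropy(st$g$psi[["a"]], st$g$psi[["b"]])
  reg <- reg + 0.5 * sum(log(2 * pi * exp(1) * VB))

  ## ---- DMFA part: local terms ----
  dmfa <- 0
  for (l in seq_len(st$L)) {
    lcl <- st$lc[[l]]
    quad <- layerQuad(st, l, idx)
    R <- st$loc$r[[l]]
    base <- lcl$Elogw - 0.5 * colSums(log(2 * pi) + lcl$Elogdelta)
    dmfa <- dmfa + sum(R * sweep(-0.5 * quad, 2, base, `+`)) -
      sum(ifelse(R > 0, R * log(R), 0)) +
      0.5 * sum(log(2 * pi * exp(1) * st$loc$z_v[[l]]))
  }
  ZL <- st$loc$z_m[[st$L]]; VL <- st$loc$z_v[[st$L]]
  dmfa <- dmfa - 0.5 * (n * ncol(ZL) * log(2 * pi) + sum(ZL^2 + VL))

  ## ---- DMFA part: global priors and entropies ----
  pr <- st$prior
  for (l in seq_len(st$L)) {
    gl <- st$g$layers[[l]]
    p <- st$arch@D[l]; q <- st$arch@D[l + 1L]; K <- st$arch@K[l]
    Elogw <- st$lc[[l]]$Elogw
    dmfa <- dmfa + dirichletLogC(rep(pr$alpha, K)) + sum((pr$alpha - 1) * Elogw) +
      dirichletEntropy(gl$dirichlet)
    E1t2 <- gl$tau2[["a"]] / gl$tau2[["b"]]
    Elogt2 <- igMeanLog(gl$tau2[["a"]], gl$tau2[["b"]])
    for (k in seq_len(K)) {
      ## component means + Cauchy auxiliaries
      Etm <- 1 / gl$tau_mu_b[, k]
      Elogtm <- log(gl$tau_mu_b[, k]) - digamma(1)
      dmfa <- dmfa + sum(-0.5 * log(2 * pi) - 0.5 * Elogtm -
                           0.5 * Etm * (gl$mu_m[, k]^2 + gl$mu_v[, k])) +
        sum(0.5 * log(pr$c_mu^2 / 2) - lg - 1.5 * Elogtm - (pr$c_mu^2 / 2) * Etm) +
        0.5 * sum(log(2 * pi * exp(1) * gl$mu_v[, k])) +
        sum(igEntropy(1, gl$tau_mu_b[, k]))
      ## layer noise + half-Cauchy auxiliaries
      E1d <- gl$delta_a[k] / gl$delta_b[, k]
      Elogd <- log(gl$delta_b[, k]) - digamma(gl$delta_a[k])
      E1a <- 1 / gl$a_delta_b[, k]
      Eloga <- log(gl$a_delta_b[, k]) - digamma(1)
      dmfa <- dmfa + sum(-0.5 * Eloga - lg - 1.5 * Elogd - E1a * E1d) +
        sum(0.5 * log(1 / pr$A_delta^2) - lg - 1.5 * Eloga - E1a / pr$A_delta^2) +
        sum(igEntropy(gl$delta_a[k], gl$delta_b[, k])) +
        sum(igEntropy(1, gl$a_delta_b[, k]))
      ## loadings + horseshoe auxiliaries (free entries)
      for (j in seq_len(p)) {
        f <- min(j, q); sf <- seq_len(f)
        Eb2 <- gl$B_m[[k]][j, sf]^2 + diag(gl$B_S[[k]][[j]])[sf]
        E1l <- 1 / gl$lam_b[[k]][j, sf]
        Elogl <- log(gl$lam_b[[k]][j, sf]) - digamma(1)
        E1n <- 1 / gl$nu_b[[k]][j, sf]
        Elogn <- log(gl$nu_b[[k]][j, sf]) - digamma(1)
        dmfa <- dmfa + sum(-0.5 * log(2 * pi) - 0.5 * (Elogl + Elogt2) -
                             0.5 * E1l * E1t2 * Eb2) +
          sum(-0.5 * Elogn - lg - 1.5 * Elogl - E1n * E1l) +
          sum(-lg - 1.5 * Elogn - E1n) +
          0.5 * (f * log(2 * pi * exp(1)) + determinant(gl$B_S[[k]][[j]])$modulus[1]) +
          sum(igEntropy(1, gl$lam_b[[k]][j, sf])) +
          sum(igEntropy(1, gl$nu_b[[k]][j, sf]))
      }
    }
    E1xi <- 1 / gl$xi_b
    Elogxi <- log(gl$xi_b) - digamma(1)
    dmfa <- dmfa + (-0.5 * Elogxi - lg - 1.5 * Elogt2 - E1xi * E1t2) +
      (0.5 * log(1 / pr$hs_scale^2) - lg - 1.5 * Elogxi - E1xi / pr$hs_scale^2) +
      igEntropy(gl$tau2[["a"]], gl$tau2[["b"]]) + igEntropy(1, gl$xi_b)
  }
  list(total = reg + dmfa, reg = reg, dmfa = dmfa)
}
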