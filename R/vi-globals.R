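## Natural-gradient updates of global variational factors. For every factor in
## exponential-family form the step is a convex combination (weight rho) of
## current natural parameters and the expected-sufficient-statistic target
## computed from the minibatch, with subject sums rescaled by n / |minibatch|.
## rho = 1 is the exact conditionally-conjugate update (CAVI).

blendIG <- function(cur, target, rho) (1 - rho) * cur + rho * target

blendGaussDiag <- function(m, v, mt, vt, rho) {
  P <- (1 - rho) / v + rho / vt
  h <- (1 - rho) * m / v + rho * mt / vt
  list(m = h / P, v = 1 / P)
}

blendGaussFull <- function(m, S, mt, St, rho) {
  P <- (1 - rho) * solve(S) + rho * solve(St)
  h <- (1 - rho) * solve(S, m) + rho * solve(St, mt)
  S2 <- solve(P)
  list(m = as.numeric(S2 %*% h), S = (S2 + t(S2)) / 2)
}

checkInDomain <- function(st) {
  ok <- st$g$sigma2[1] > 0 && st$g$sigma2[2] > 0 && st$g$psi[2] > 0
  for (l in seq_len(st$L)) {
    gl <- st$g$layers[[l]]
    ok <- ok && all(gl$dirichlet > 0) && all(gl$delta_a > 0) && all(gl$delta_b > 0) &&
      all(gl$mu_v > 0) && all(gl$a_delta_b > 0) && all(gl$tau_mu_b > 0) &&
      gl$tau2[2] > 0 && gl$xi_b > 0
  }
  ok
}

globalStep <- function(st, cache, idx, rho) {
  arch <- st$arch
  scale <- st$n / length(idx)
  prior <- st$prior
  for (l in seq_len(st$L)) {
    gl <- st$g$layers[[l]]
    p <- arch@D[l]; q <- arch@D[l + 1L]; K <- arch@K[l]
    R <- st$loc$r[[l]][idx, , drop = FALSE]
    xin <- layerInput(st, l, idx)
    MX <- xin$M; VX <- xin$V
    MW <- st$loc$z_m[[l]][idx, , drop = FALSE]
    VW <- st$loc$z_v[[l]][idx, , drop = FALSE]
    Nk <- scale * colSums(R)
    E1delta <- sweep(1 / gl$delta_b, 2, gl$delta_a, `*`)
    ## mixture weights
    gl$dirichlet <- (1 - rho) * gl$dirichlet + rho * (prior$alpha + Nk)
    for (k in seq_len(K)) {
      rk <- R[, k]
      Wbar <- scale * (crossprod(MW * rk, MW) + diag(colSums(rk * VW), q))
      sw <- scale * colSums(rk * MW)
      ## mean shifts (uses current loadings)
      Bmw <- as.numeric(gl$B_m[[k]] %*% sw)
      Pt <- 1 / gl$tau_mu_b[, k] + E1delta[, k] * pmax(Nk[k], 1e-12)
      ht <- E1delta[, k] * (scale * colSums(rk * MX) - Bmw)
      upd <- blendGaussDiag(gl$mu_m[, k], gl$mu_v[, k], ht / Pt, 1 / Pt, rho)
      gl$mu_m[, k] <- upd$m; gl$mu_v[, k] <- upd$v
      ## loadings, row by row (uses fresh mean shifts)
      MXc <- sweep(MX, 2, gl$mu_m[, k])
      Uc <- scale * crossprod(MW, rk * MXc)     # q x p
      E1l2 <- 1 / gl$lam_b[[k]]                 # IG(1, b): E[1/lambda2] = 1/b
      E1t2 <- gl$tau2[["a"]] / gl$tau2[["b"]]
      for (j in seq_len(p)) {
        f <- min(j, q)
        sf <- seq_len(f)
        Pt <- E1delta[j, k] * Wbar[sf, sf, drop = FALSE] + diag(E1l2[j, sf] * E1t2, f)
        ht <- E1delta[j, k] * Uc[sf, j]
        St <- solve(Pt); St <- (St + t(St)) / 2
        upd <- blendGaussFull(gl$B_m[[k]][j, sf], gl$B_S[[k]][[j]],
                              as.numeric(St %*% ht), St, rho)
        gl$B_m[[k]][j, sf] <- upd$m
        gl$B_S[[k]][[j]] <- upd$S
      }
      ## layer noise (uses fresh means and loadings)
      P1 <- MW %*% t(gl$B_m[[k]])
      A1 <- scale * colSums(rk * (MXc^2 + VX)) + Nk[k] * gl$mu_v[, k]
      A2 <- scale * colSums(rk * (MXc * P1))
      A3 <- vapply(seq_len(p), function(j) {
        f <- min(j, q)
        EBB <- gl$B_S[[k]][[j]] + tcrossprod(gl$B_m[[k]][j, seq_len(f)])
        sum(EBB * Wbar[seq_len(f), seq_len(f)])
      }, numeric(1))
      Skj <- pmax(A1 - 2 * A2 + A3, 0)
      at <- 0.5 + Nk[k] / 2
      bt <- 1 / gl$a_delta_b[, k] + Skj / 2
      gl$delta_a[k] <- blendIG(gl$delta_a[k], at, rho)
      gl$delta_b[, k] <- blendIG(gl$delta_b[, k], bt, rho)
      ## auxiliaries
      E1d_new <- gl$delta_a[k] / gl$delta_b[, k]
      gl$a_delta_b[, k] <- blendIG(gl$a_delta_b[, k], 1 / prior$A_delta^2 + E1d_new, rho)
      gl$tau_mu_b[, k] <- blendIG(gl$tau_mu_b[, k],
                                  prior$c_mu^2 / 2 + (gl$mu_m[, k]^2 + gl$mu_v[, k]) / 2, rho)
      Eb2 <- gl$B_m[[k]]^2
      for (j in seq_len(p)) {
        f <- min(j, q)
        Eb2[j, seq_len(f)] <- Eb2[j, seq_len(f)] + diag(gl$B_S[[k]][[j]])[seq_len(f)]
      }
      gl$lam_b[[k]] <- blendIG(gl$lam_b[[k]], 1 / gl$nu_b[[k]] + Eb2 * E1t2 / 2, rho)
      gl$nu_b[[k]] <- blendIG(gl$nu_b[[k]], 1 + 1 / gl$lam_b[[k]], rho)
    }
    ## global horseshoe scale of the layer
    mask <- lowerTriMask(p, q)
    ssum <- 0
    for (k in seq_len(K)) {
      Eb2 <- gl$B_m[[k]]^2
      for (j in seq_len(p)) {
        f <- min(j, q)
        Eb2[j, seq_len(f)] <- Eb2[j, seq_len(f)] + diag(gl$B_S[[k]][[j]])[seq_len(f)]
      }
      ssum <- ssum + sum((Eb2 / gl$lam_b[[k]])[mask])
    }
    nfree <- freeCount(p, q) * K
    gl$tau2 <- c(a = blendIG(gl$tau2[["a"]], (1 + nfree) / 2, rho),
                 b = blendIG(gl$tau2[["b"]], 1 / gl$xi_b + ssum / 2, rho))
    gl$xi_b <- blendIG(gl$xi_b, 1 / prior$hs_scale^2 + gl$tau2[["a"]] / gl$tau2[["b"]], rho)
    st$g$layers[[l]] <- gl
    refreshLayerCache(st, l)
  }
  ## error variance and its auxiliary
  MB <- st$loc$beta_m[idx, , drop = FALSE]
  VB <- st$loc$beta_v[idx, , drop = FALSE]
  qf <- 0
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    b <- MB[ii, ]
    qf <- qf + cache$yty[i] - 2 * sum(cache$Bty[, i] * b) +
      sum(b * (cache$BtB[, , i] %*% b)) + sum(diag(cache$BtB[, , i]) * VB[ii, ])
  }
  at <- 0.5 + scale * sum(cache$ni[idx]) / 2
  bt <- st$E1psi + scale * qf / 2
  st$g$sigma2 <- c(a = blendIG(st$g$sigma2[["a"]], at, rho),
                   b = blendIG(st$g$sigma2[["b"]], bt, rho))
  st$g$psi <- c(a = 1, b = blendIG(st$g$psi[["b"]],
                                   1 / st$prior$A^2 + st$g$sigma2[["a"]] / st$g$sigma2[["b"]], rho))
  refreshSigmaCache(st)
  invisible(st)
}

#' One natural-gradient global step (with domain guard)
#'
#' Steps all global factors toward the minibatch target; if a step leaves the
#' factor domain the step size is halved (at most 10 times) before failing.
#'
#' @keywords internal
naturalGradientGlobalStep <- function(st, cache, idx, rho) {
  snapshot <- list(g = st$g, lc = st$lc, Es2inv = st$Es2inv, Elogs2 = st$Elogs2,
                   E1psi = st$E1psi, Elogpsi = st$Elogpsi)
  for (h in 0:10) {
    globalStep(st, cache, idx, rho)
    if (checkInDomain(st)) return(invisible(st))
    warning("global step left the factor domain; halving step size")
    st$g <- snapshot$g; st$lc <- snapshot$lc
    st$Es2inv <- snapshot$Es2inv; st$Elogs2 <- snapshot$Elogs2
    st$E1psi <- snapshot$E1psi; st$Elogpsi <- snapshot$Elogpsi
    rho <- rho / 2
  }
  stop("global step failed to stay in domain after 10 halvings")
}
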