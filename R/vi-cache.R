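## Internal data-side precomputations and variational-state caches.
##
## The variational state lives in an environment `st` with fields:
##   arch, prior, control, n, d, L
##   g$sigma2, g$psi          IG factors c(a, b)
##   g$layers[[l]]            list(dirichlet, mu_m, mu_v, B_m, B_S,
##                                 delta_a, delta_b, a_delta_b, tau_mu_b,
##                                 lam_b, nu_b, tau2, xi_b)
##   loc$beta_m, loc$beta_v   n x d
##   loc$z_m[[l]], loc$z_v[[l]]  n x D(l)
##   loc$r[[l]]               n x K(l) responsibilities
##   lc[[l]]                  derived layer expectations (refreshLayerCache)

buildDataCache <- function(data, basis) {
  n <- nSubjects(data)
  d <- basis@d
  B <- vector("list", n); BtB <- array(0, c(d, d, n)); Bty <- matrix(0, d, n)
  yty <- numeric(n); ni <- obsCounts(data)
  for (i in seq_len(n)) {
    Bi <- designMatrix(basis, data@times[[i]])
    yi <- data@values[[i]]
    B[[i]] <- Bi
    BtB[, , i] <- crossprod(Bi)
    Bty[, i] <- crossprod(Bi, yi)
    yty[i] <- sum(yi^2)
  }
  tr <- range(unlist(data@times))
  grid <- seq(max(tr[1], basis@domain[1]), min(tr[2], basis@domain[2]),
              length.out = 50L)
  list(B = B, BtB = BtB, Bty = Bty, yty = yty, ni = ni, y = data@values,
       n = n, d = d, Ntot = sum(ni), Bgrid = designMatrix(basis, grid))
}

freeCount <- function(p, q) sum(pmin(seq_len(p), q))

## Refresh cached expectations derived from layer l's global factors.
refreshLayerCache <- function(st, l) {
  gl <- st$g$layers[[l]]
  p <- st$arch@D[l]; q <- st$arch@D[l + 1L]; K <- st$arch@K[l]
  E1delta <- sweep(1 / gl$delta_b, 2, gl$delta_a, `*`)
  Elogdelta <- sweep(log(gl$delta_b), 2, digamma(gl$delta_a), `-`)
  G <- vector("list", K); EBBrow <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- vector("list", p)
    Gk <- matrix(0, q, q)
    for (j in seq_len(p)) {
      f <- min(j, q)
      mj <- gl$B_m[[k]][j, seq_len(f)]
      EBB <- gl$B_S[[k]][[j]] + tcrossprod(mj)
      rows[[j]] <- EBB
      Gk[seq_len(f), seq_len(f)] <- Gk[seq_len(f), seq_len(f)] + E1delta[j, k] * EBB
    }
    G[[k]] <- Gk
    EBBrow[[k]] <- rows
  }
  st$lc[[l]] <- list(
    Elogw = dirichletMeanLog(gl$dirichlet),
    E1delta = E1delta, Elogdelta = Elogdelta,
    mB = lapply(gl$B_m, identity),
    EBBrow = EBBrow, G = G,
    Gflat = matrix(unlist(lapply(G, as.numeric)), nrow = K, byrow = TRUE))
  invisible(st)
}

refreshSigmaCache <- function(st) {
  st$Es2inv <- st$g$sigma2[["a"]] / st$g$sigma2[["b"]]
  st$Elogs2 <- log(st$g$sigma2[["b"]]) - digamma(st$g$sigma2[["a"]])
  st$E1psi <- st$g$psi[["a"]] / st$g$psi[["b"]]
  st$Elogpsi <- log(st$g$psi[["b"]]) - digamma(st$g$psi[["a"]])
  invisible(st)
}

## x-side (layer input) local moments for layer l over subjects idx.
layerInput <- function(st, l, idx) {
  if (l == 1L) list(M = st$loc$beta_m[idx, , drop = FALSE],
                    V = st$loc$beta_v[idx, , drop = FALSE])
  else list(M = st$loc$z_m[[l - 1L]][idx, , drop = FALSE],
            V = st$loc$z_v[[l - 1L]][idx, , drop = FALSE])
}

## Per-(subject, component) expected quadratic forms for layer l:
## quad[i, k] = sum_j E1delta[j,k] * E[(x_j - mu_jk - B_kj w)^2].
## Also returns per-component pieces reused by updates.
layerQuad <- function(st, l, idx) {
  K <- st$arch@K[l]; q <- st$arch@D[l + 1L]
  xin <- layerInput(st, l, idx)
  MX <- xin$M; VX <- xin$V
  MW <- st$loc$z_m[[l]][idx, , drop = FALSE]
  VW <- st$loc$z_v[[l]][idx, , drop = FALSE]
  gl <- st$g$layers[[l]]; lcl <- st$lc[[l]]
  m <- length(idx)
  quad <- matrix(0, m, K)
  for (k in seq_len(K)) {
    MXc <- sweep(MX, 2, gl$mu_m[, k])
    P1 <- MW %*% t(lcl$mB[[k]])                      # (B_k w)_j
    e1 <- lcl$E1delta[, k]
    t1 <- (MXc^2 + VX) %*% e1 + sum(gl$mu_v[, k] * e1)
    t2 <- rowSums((MXc %*% diag(e1, length(e1))) * P1)
    Gk <- lcl$G[[k]]
    t3 <- rowSums((MW %*% Gk) * MW) + VW %*% diag(Gk)
    quad[, k] <- t1 - 2 * t2 + t3
  }
  quad
}
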