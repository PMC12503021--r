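## Local (per-subject) coordinate-ascent updates: responsibilities per layer,
## the coefficient factor q(beta_i), and latent factors q(z_i^(l)). Each block
## is set to its exact optimum within the (diagonal-Gaussian / categorical)
## family given the other factors, so every sweep is monotone in the local
## ELBO contribution.

updateResponsibilities <- function(st, idx, l) {
  lcl <- st$lc[[l]]
  quad <- layerQuad(st, l, idx)
  base <- lcl$Elogw - 0.5 * colSums(log(2 * pi) + lcl$Elogdelta)
  lr <- sweep(-0.5 * quad, 2, base, `+`)
  lr <- lr - apply(lr, 1, max)
  r <- exp(lr)
  r <- r / rowSums(r)
  if (any(!is.finite(r))) stop("numerical error: non-finite responsibilities (subjects ",
                               paste(idx[!is.finite(rowSums(r))], collapse = ","), ")")
  st$loc$r[[l]][idx, ] <- r
  invisible(st)
}

## Accumulate  sum_k r[,k] * E1delta[,k] * (mu_k + B_k mw)_j  (m x p) --
## the linear pull a layer exerts on its input variable.
layerPull <- function(st, l, idx) {
  gl <- st$g$layers[[l]]; lcl <- st$lc[[l]]
  R <- st$loc$r[[l]][idx, , drop = FALSE]
  MW <- st$loc$z_m[[l]][idx, , drop = FALSE]
  p <- st$arch@D[l]
  H <- matrix(0, length(idx), p)
  for (k in seq_len(st$arch@K[l])) {
    pred <- sweep(MW %*% t(lcl$mB[[k]]), 2, gl$mu_m[, k], `+`)
    H <- H + (R[, k] * pred) %*% diag(lcl$E1delta[, k], p)
  }
  H
}

## Diagonal precision a layer exerts on its input variable (m x p).
layerDiagPrec <- function(st, l, idx) {
  st$loc$r[[l]][idx, , drop = FALSE] %*% t(st$lc[[l]]$E1delta)
}

updateBeta <- function(st, cache, idx) {
  d <- st$d
  Dl <- layerDiagPrec(st, 1L, idx)
  Hl <- layerPull(st, 1L, idx)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    P <- st$Es2inv * cache$BtB[, , i]
    diag(P) <- diag(P) + Dl[ii, ]
    h <- st$Es2inv * cache$Bty[, i] + Hl[ii, ]
    R <- safeChol(P, label = "q(beta) precision")
    st$loc$beta_m[i, ] <- backsolve(R, backsolve(R, h, transpose = TRUE))
    st$loc$beta_v[i, ] <- 1 / diag(P)
  }
  invisible(st)
}

updateZ <- function(st, idx, l) {
  arch <- st$arch
  q <- arch@D[l + 1L]; K <- arch@K[l]
  gl <- st$g$layers[[l]]; lcl <- st$lc[[l]]
  R <- st$loc$r[[l]][idx, , drop = FALSE]
  xin <- layerInput(st, l, idx)
  m <- length(idx)
  ## pull from layer l (z^(l) as the factor input)
  Hw <- matrix(0, m, q)
  for (k in seq_len(K)) {
    MXc <- sweep(xin$M, 2, gl$mu_m[, k])
    Hw <- Hw + (R[, k] * (MXc %*% diag(lcl$E1delta[, k], arch@D[l]))) %*% lcl$mB[[k]]
  }
  ## pull and precision from layer l+1 (z^(l) as that layer's output), or the
  ## standard-normal top prior
  if (l < st$L) {
    Dx <- layerDiagPrec(st, l + 1L, idx)
    Hx <- layerPull(st, l + 1L, idx)
  } else {
    Dx <- matrix(1, m, q)
    Hx <- matrix(0, m, q)
  }
  Pall <- R %*% lcl$Gflat          # m x q^2, row-wise flattened G sums
  for (ii in seq_len(m)) {
    P <- matrix(Pall[ii, ], q, q)
    diag(P) <- diag(P) + Dx[ii, ]
    h <- Hw[ii, ] + Hx[ii, ]
    Rch <- safeChol(P, label = "q(z) precision")
    st$loc$z_m[[l]][idx[ii], ] <- backsolve(Rch, backsolve(Rch, h, transpose = TRUE))
    st$loc$z_v[[l]][idx[ii], ] <- 1 / diag(P)
  }
  invisible(st)
}

## Per-subject local ELBO contribution (terms involving subject i's factors),
## used for inner-loop convergence and monotonicity checks.
localELBOvec <- function(st, cache, idx) {
  m <- length(idx)
  MB <- st$loc$beta_m[idx, , drop = FALSE]
  VB <- st$loc$beta_v[idx, , drop = FALSE]
  ## likelihood term
  qf <- numeric(m)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    b <- MB[ii, ]
    qf[ii] <- cache$yty[i] - 2 * sum(cache$Bty[, i] * b) +
      sum(b * (cache$BtB[, , i] %*% b)) + sum(diag(cache$BtB[, , i]) * VB[ii, ])
  }
  out <- -0.5 * cache$ni[idx] * (log(2 * pi) + st$Elogs2) - 0.5 * st$Es2inv * qf
  ## layer terms + responsibility entropies
  for (l in seq_len(st$L)) {
    lcl <- st$lc[[l]]
    quad <- layerQuad(st, l, idx)
    R <- st$loc$r[[l]][idx, , drop = FALSE]
    base <- lcl$Elogw - 0.5 * colSums(log(2 * pi) + lcl$Elogdelta)
    out <- out + rowSums(R * sweep(-0.5 * quad, 2, base, `+`)) -
      rowSums(ifelse(R > 0, R * log(R), 0))
    ## z entropy
    out <- out + 0.5 * rowSums(log(2 * pi * exp(1) * st$loc$z_v[[l]][idx, , drop = FALSE]))
  }
  ## top-layer prior
  ZL <- st$loc$z_m[[st$L]][idx, , drop = FALSE]
  VL <- st$loc$z_v[[st$L]][idx, , drop = FALSE]
  out <- out - 0.5 * (ncol(ZL) * log(2 * pi) + rowSums(ZL^2 + VL))
  ## beta entropy
  out + 0.5 * rowSums(log(2 * pi * exp(1) * VB))
}

#' One full pass of local updates for a subject subset
#'
#' Block coordinate ascent over responsibilities, q(beta_i) and q(z_i^(l)),
#' iterated until the summed local ELBO change falls below \code{inner_tol}
#' or \code{n_inner} sweeps.
#'
#' @keywords internal
updateLocalsBatch <- function(st, cache, idx, n_inner = st$control$n_inner,
                              inner_tol = st$control$inner_tol, trace = FALSE) {
  objs <- NULL
  prev <- -Inf
  for (s in seq_len(n_inner)) {
    for (l in seq_len(st$L)) updateResponsibilities(st, idx, l)
    updateBeta(st, cache, idx)
    for (l in seq_len(st$L)) updateZ(st, idx, l)
    cur <- localELBOvec(st, cache, idx)
    tot <- sum(cur)
    if (trace) objs <- rbind(objs, cur)
    if (is.finite(prev) && tot - prev < inner_tol * length(idx)) break
    prev <- tot
  }
  if (trace) objs else invisible(prev)
}
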