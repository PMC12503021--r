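## Synthetic data-generating processes used as the package's test surface:
## three benchmark designs plus a generic generator that simulates from a
## mixture-model truth for parameter-recovery experiments. All generators are
## seed-deterministic.

dgpOutput <- function(data, truth, labels = NULL, params = NULL, heldout = NULL) {
  structure(list(data = data, truth = truth, labels = labels, params = params,
                 heldout = heldout), class = "DGPOutput")
}

#' Two-group sinusoidal curves with Karhunen-Loeve functional noise
#'
#' Per subject: 10 sorted uniform times on [0, 1]; group sign g_i uniform on
#' {-1, +1}; y = g_i sin(4 pi t) + 2 sum_{k=1}^4 xi_k sin(k pi t) + eps,
#' with xi sds (0.1, 0.045, 0.01, 0.001) and eps sd 0.3. Two latent groups
#' with means +-sin(4 pi t).
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return a DGPOutput; \code{truth} holds the noise-free subject curves and
#'   \code{labels} the group signs.
#' @export
generateDGP1 <- function(n_subjects = 600L, seed = 1L) {
  set.seed(seed)
  xisd <- c(0.1, 0.045, 0.01, 0.001)
  ids <- sprintf("s%04d", seq_len(n_subjects))
  times <- vector("list", n_subjects); values <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  g <- sample(c(-1, 1), n_subjects, replace = TRUE)
  ximat <- matrix(0, n_subjects, 4)
  for (i in seq_len(n_subjects)) {
    t <- sort(stats::runif(10))
    xi <- stats::rnorm(4, 0, xisd)
    ximat[i, ] <- xi
    f <- g[i] * sin(4 * pi * t) +
      2 * as.numeric(sin(outer(t, 1:4) * pi) %*% xi)
    times[[i]] <- t
    truth[[i]] <- f
    values[[i]] <- f + stats::rnorm(10, 0, 0.3)
  }
  dgpOutput(longitudinalData(ids, times, values), truth, labels = g,
            params = data.frame(g = g, xi1 = ximat[, 1], xi2 = ximat[, 2],
                                xi3 = ximat[, 3], xi4 = ximat[, 4]))
}

## Euler-Maruyama integration of the stochastic Van der Pol system for a set
## of subjects simultaneously; returns the f paths on the grid (columns are
## subjects). Divergent paths show up as non-finite columns.
vdpPaths <- function(theta, t_end, dt, diffusion) {
  n <- length(theta)
  steps <- round(t_end / dt)
  f <- rep(1, n); g <- rep(0.1, n)
  F <- matrix(NA_real_, steps + 1L, n)
  F[1L, ] <- f
  sdt <- sqrt(dt)
  for (s in seq_len(steps)) {
    fn <- f + dt * g + diffusion * sdt * stats::rnorm(n)
    gn <- g + dt * (theta * (1 - f^2) * g - f) + diffusion * sdt * stats::rnorm(n)
    bad <- !is.finite(fn) | !is.finite(gn) | abs(fn) > 1e6
    fn[bad] <- NA_real_; gn[bad] <- NA_real_
    f <- fn; g <- gn
    F[s + 1L, ] <- f
  }
  F
}

#' Stochastic Van der Pol oscillator trajectories
#'
#' Per subject: theta_i = exp(U(1, 5)); the system
#' df = g dt + 0.5 dW_f, dg = (theta (1 - f^2) g - f) dt + 0.5 dW_g with
#' f(0) = 1, g(0) = 0.1 is integrated by Euler-Maruyama from t = 0; n_i
#' uniform on {15, ..., 25} observation times uniform on [10, 20] are
#' snapped to the integration grid; y = f(t) with no extra observation
#' noise. Subjects whose path blows up (|f| > 1e6) are regenerated with a
#' halved step.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param dt Euler-Maruyama step.
#' @param diffusion diffusion coefficient on both coordinates (0 gives the
#'   deterministic oscillator).
#' @return a DGPOutput; \code{params} holds theta_i.
#' @export
generateDGP2 <- function(n_subjects = 100L, seed = 1L, dt = 1e-3, diffusion = 0.5) {
  set.seed(seed)
  theta <- exp(stats::runif(n_subjects, 1, 5))
  ni <- sample(15:25, n_subjects, replace = TRUE)
  tobs <- lapply(seq_len(n_subjects), function(i) sort(stats::runif(ni[i], 10, 20)))
  F <- vdpPaths(theta, 20, dt, diffusion)
  dts <- rep(dt, n_subjects)
  bad <- which(!is.finite(F[nrow(F), ]))
  while (length(bad)) {
    dts[bad] <- dts[bad] / 2
    message("dmlmm: DGP 2 path blew up for ", length(bad),
            " subject(s); retrying with halved step")
    Fb <- vdpPaths(theta[bad], 20, dts[bad][1], diffusion)
    still <- !is.finite(Fb[nrow(Fb), ])
    ## paste repaired columns back on the original grid by index scaling
    ratio <- round(dt / dts[bad][1])
    for (j in seq_along(bad)) {
      if (still[j]) next
      F[, bad[j]] <- Fb[seq(1L, nrow(Fb), by = ratio), j]
    }
    bad <- bad[still]
  }
  ids <- sprintf("s%04d", seq_len(n_subjects))
  times <- vector("list", n_subjects); values <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    tsnap <- round(tobs[[i]] / dt) * dt
    times[[i]] <- tsnap
    values[[i]] <- F[round(tsnap / dt) + 1L, i]
  }
  dgpOutput(longitudinalData(ids, times, values), truth = values,
            params = theta)
}

#' Trigonometric grid curves with removed entries (imputation design)
#'
#' Forty grid positions j = 1..40 mapped to t = (j - 1)/39. Per subject:
#' y_j = b1 cos(w1 pi t) + b2 sin(w2 pi t) + eps with b1, b2 uniform on
#' {1, 0.1}, w1 on {1, 2, 3}, w2 on {7, 8, 9} and eps sd 0.1 -- 36 latent
#' clusters. A uniform count in {15, ..., 20} of positions is removed per
#' subject (without replacement); the removed observations are the held-out
#' target.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return a DGPOutput; \code{heldout} holds per-subject removed times,
#'   observed values at those times, and noise-free values; \code{labels} the
#'   (b1, b2, w1, w2) combination as a string.
#' @export
generateDGP3 <- function(n_subjects = 120L, seed = 1L) {
  set.seed(seed)
  tgrid <- (0:39) / 39
  ids <- sprintf("s%04d", seq_len(n_subjects))
  b1 <- sample(c(1, 0.1), n_subjects, replace = TRUE)
  b2 <- sample(c(1, 0.1), n_subjects, replace = TRUE)
  w1 <- sample(1:3, n_subjects, replace = TRUE)
  w2 <- sample(7:9, n_subjects, replace = TRUE)
  times <- vector("list", n_subjects); values <- vector("list", n_subjects)
  truth <- vector("list", n_subjects); heldout <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    f <- b1[i] * cos(w1[i] * pi * tgrid) + b2[i] * sin(w2[i] * pi * tgrid)
    y <- f + stats::rnorm(40, 0, 0.1)
    nrem <- sample(15:20, 1L)
    rem <- sort(sample.int(40, nrem))
    keep <- setdiff(seq_len(40L), rem)
    times[[i]] <- tgrid[keep]
    values[[i]] <- y[keep]
    truth[[i]] <- f[keep]
    heldout[[i]] <- list(times = tgrid[rem], values = y[rem], truth = f[rem])
  }
  dgpOutput(longitudinalData(ids, times, values), truth,
            labels = sprintf("%g-%g-%d-%d", b1, b2, w1, w2),
            params = data.frame(b1 = b1, b2 = b2, w1 = w1, w2 = w2),
            heldout = heldout)
}

#' Simulate longitudinal data from a mixture-model truth
#'
#' Draws coefficient vectors from a Gaussian-mixture truth, observation times
#' from the basis domain, and responses y = B(t) beta + N(0, sigma2 I).
#' Used for parameter-recovery experiments where the truth is known by
#' construction.
#'
#' @param gmm a \linkS4class{GaussianMixture} truth (or a
#'   \linkS4class{DMLMMFit}, whose gmm/sigma2/basis are used).
#' @param sigma2 error variance (ignored when gmm is a fit).
#' @param basis a \linkS4class{BasisSpec} (ignored when gmm is a fit).
#' @param n_subjects number of subjects.
#' @param ni observation count per subject: scalar, vector, or function(n).
#' @param seed integer seed.
#' @return a DGPOutput; \code{params} holds the true coefficients and
#'   \code{labels} the true mixture components.
#' @export
generateFromDMLMM <- function(gmm, sigma2 = NULL, basis = NULL, n_subjects = 100L,
                              ni = 10L, seed = 1L) {
  if (is(gmm, "DMLMMFit")) {
    sigma2 <- gmm@sigma2; basis <- gmm@basis; gmm <- gmm@gmm
  }
  stopifnot(is(gmm, "GaussianMixture"), sigma2 >= 0, is(basis, "BasisSpec"))
  set.seed(seed)
  nvec <- if (is.function(ni)) ni(n_subjects) else rep(ni, length.out = n_subjects)
  draws <- sampleGMM(gmm, n_subjects)
  ids <- sprintf("s%04d", seq_len(n_subjects))
  times <- vector("list", n_subjects); values <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    t <- sort(stats::runif(nvec[i], basis@domain[1], basis@domain[2]))
    B <- designMatrix(basis, t)
    f <- as.numeric(B %*% draws$x[i, ])
    times[[i]] <- t
    truth[[i]] <- f
    values[[i]] <- f + stats::rnorm(nvec[i], 0, sqrt(sigma2))
  }
  dgpOutput(longitudinalData(ids, times, values), truth,
            labels = draws$component,
            params = draws$x)
}
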