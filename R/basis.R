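#' Legendre polynomial basis
#'
#' Unnormalized Legendre polynomials P_0, ..., P_{d-1} evaluated on the domain
#' affinely rescaled to [-1, 1]. The coefficient vector absorbs any scale, so
#' the unnormalized convention is fixed for determinism.
#'
#' @param d basis dimension (polynomial degrees 0..d-1).
#' @param domain numeric length-2 (t_min, t_max).
#' @return a \linkS4class{BasisSpec}.
#' @export
legendreBasis <- function(d, domain = c(0, 1)) {
  new("BasisSpec", kind = "legendre", d = as.integer(d), domain = as.numeric(domain),
      period = NA_real_, nSeasonal = 0L, nTrend = 0L)
}

#' Seasonal B-spline basis
#'
#' Periodic cubic B-splines of a given period (evaluated at t mod period)
#' concatenated with cubic B-splines over the whole domain with equispaced
#' interior knots. Used when responses carry a seasonal signal on top of a
#' smooth trend.
#'
#' @param d total basis dimension.
#' @param period seasonal period in time units.
#' @param nSeasonal number of periodic columns (d - nSeasonal trend columns).
#' @param domain numeric length-2 (t_min, t_max).
#' @return a \linkS4class{BasisSpec}.
#' @export
seasonalSplineBasis <- function(d, period, nSeasonal, domain) {
  nTrend <- as.integer(d) - as.integer(nSeasonal)
  if (nTrend != 0L && nTrend < 4L)
    stop("cubic trend block needs nTrend = 0 or nTrend >= 4")
  new("BasisSpec", kind = "bspline_seasonal", d = as.integer(d),
      domain = as.numeric(domain), period = as.numeric(period),
      nSeasonal = as.integer(nSeasonal), nTrend = nTrend)
}

legendreCols <- function(u, d) {
  m <- length(u)
  P <- matrix(0, m, d)
  P[, 1L] <- 1
  if (d >= 2L) P[, 2L] <- u
  if (d >= 3L) {
    for (n in 1:(d - 2L)) {
      P[, n + 2L] <- ((2 * n + 1) * u * P[, n + 1L] - n * P[, n]) / (n + 1)
    }
  }
  P
}

periodicSplineCols <- function(t, period, m) {
  h <- period / m
  u <- t %% period
  knots <- h * (-4L:(m + 4L))
  D <- splines::splineDesign(knots, u, ord = 4L, outer.ok = TRUE)
  ## B-spline i (support [knots_i, knots_{i+4})) maps to periodic column
  ## (i mod m); sum aliased columns.
  nb <- ncol(D)                      # = length(knots) - 4
  out <- matrix(0, length(u), m)
  for (j in seq_len(nb)) {
    i <- j - 5L                      # knot start index of this spline
    out[, (i %% m) + 1L] <- out[, (i %% m) + 1L] + D[, j]
  }
  out
}

trendSplineCols <- function(t, domain, nTrend) {
  k <- nTrend - 4L
  interior <- if (k > 0L) seq(domain[1], domain[2], length.out = k + 2L)[-c(1L, k + 2L)] else numeric()
  splines::bs(t, knots = interior, degree = 3L, intercept = TRUE,
              Boundary.knots = domain)[, , drop = FALSE]
}

#' Evaluate the design matrix B(t)
#'
#' Row j of the returned matrix is the basis evaluated at t[j]. Times outside
#' the stored domain are an error (no extrapolation); an empty time vector
#' yields a valid 0 x d matrix.
#'
#' @param spec a \linkS4class{BasisSpec}.
#' @param t numeric vector of evaluation times.
#' @return length(t) x d numeric matrix.
#' @export
designMatrix <- function(spec, t) {
  stopifnot(is(spec, "BasisSpec"))
  t <- as.numeric(t)
  if (length(t) == 0L) return(matrix(0, 0L, spec@d))
  tol <- 1e-9 * max(1, abs(spec@domain))
  if (any(t < spec@domain[1] - tol) || any(t > spec@domain[2] + tol))
    stop("domain error: evaluation times outside [", spec@domain[1], ", ",
         spec@domain[2], "]")
  t <- pmin(pmax(t, spec@domain[1]), spec@domain[2])
  if (spec@kind == "legendre") {
    u <- 2 * (t - spec@domain[1]) / diff(spec@domain) - 1
    B <- legendreCols(u, spec@d)
  } else {
    Bs <- periodicSplineCols(t, spec@period, spec@nSeasonal)
    if (spec@nTrend > 0L) {
      Bt <- trendSplineCols(t, spec@domain, spec@nTrend)
      B <- cbind(Bs, Bt)
    } else B <- Bs
  }
  dimnames(B) <- NULL
  B
}
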