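## Small numerical helpers shared across the package.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain -Inf).
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log-sum-exp for a matrix.
rowLogSumExp <- function(X) {
  m <- apply(X, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(X[ok, , drop = FALSE] - m[ok])))
  out
}

## Cholesky with diagonal jitter fallback. Near-singular matrices get 1e-8 added
## to the diagonal before a second attempt; failure after jitter is an error.
safeChol <- function(S, jitter = 1e-8, label = "covariance") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(S + diag(jitter, nrow(S))), error = function(e) NULL)
    if (is.null(R)) {
      stop("matrix for ", label, " is not positive definite (even after jitter)")
    }
    if (isTRUE(getOption("dmlmm.verbose", FALSE))) {
      message("dmlmm: applied diagonal jitter ", jitter, " to ", label)
    }
  }
  R
}

## log N(x; mu, S) via Cholesky; x may be a matrix (rows = points).
mvnLogpdf <- function(x, mu, S) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  if (d == 1L) {
    s2 <- as.numeric(S)
    return(stats::dnorm(x[, 1L], mean = as.numeric(mu), sd = sqrt(s2), log = TRUE))
  }
  R <- safeChol(S, label = "mvn covariance")
  z <- backsolve(R, t(x) - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

## Inverse-gamma (shape a, rate b; density ~ x^{-a-1} exp(-b/x)) helpers.
igLogpdf <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
igMeanInv <- function(a, b) a / b            # E[1/x]
igMeanLog <- function(a, b) log(b) - digamma(a)  # E[log x]
igEntropy <- function(a, b) a + log(b) + lgamma(a) - (1 + a) * digamma(a)

## Dirichlet helpers (concentration vector c).
dirichletMeanLog <- function(cv) digamma(cv) - digamma(sum(cv))
dirichletEntropy <- function(cv) {
  c0 <- sum(cv)
  sum(lgamma(cv)) - lgamma(c0) + (c0 - length(cv)) * digamma(c0) -
    sum((cv - 1) * digamma(cv))
}
dirichletLogC <- function(cv) lgamma(sum(cv)) - sum(lgamma(cv))

## Derive a bounded child seed from (seed, offset); stays below 2^31.
childSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
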