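#' Prior-data conflict check for within-subject prediction
#'
#' The divergence statistic G(y_past) is the Kullback-Leibler divergence from
#' the conditional predictive law of the future segment given the past to the
#' marginal predictive law of the future segment, estimated by Monte Carlo
#' with draws from the conditional. The reference distribution of G is built
#' from replicate past segments drawn from the model's own marginal
#' predictive; the tail probability is the add-one-corrected fraction of
#' replicates with G at least the observed statistic. A small p indicates the
#' observed past segment is surprising under the model.
#'
#' @param model a \linkS4class{DMLMMFit}.
#' @param y_past observed past-segment responses.
#' @param t_past past-segment times (same length, nonempty).
#' @param t_future future-segment times (nonempty).
#' @param n_sim number of replicate past segments (values below 20 give a
#'   coarse p-value and trigger a warning).
#' @param n_kl Monte-Carlo draws per KL estimate.
#' @param seed optional integer seed.
#' @return list with \code{p}, \code{G_obs}, \code{G_ref} (replicate
#'   statistics) and \code{G_obs_se} (Monte-Carlo standard error of G_obs).
#' @export
conflictPvalue <- function(model, y_past, t_past, t_future,
                           n_sim = 200L, n_kl = 2000L, seed = NULL) {
  if (!length(t_past) || !length(t_future))
    stop("both the past and future segments must be nonempty")
  stopifnot(length(y_past) == length(t_past))
  if (n_sim < 20L) warning("n_sim < 20 gives a coarse p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  marg_future <- asGaussianMixture(marginalPredictive(model, t_future))
  klStat <- function(y) {
    cond <- asGaussianMixture(conditionalPredictive(model, y, t_past, t_future))
    draws <- sampleGMM(cond, n_kl)$x
    diffs <- gmmLogpdf(cond, draws) - gmmLogpdf(marg_future, draws)
    c(mean(diffs), stats::sd(diffs) / sqrt(n_kl))
  }
  obs <- klStat(y_past)
  marg_past <- asGaussianMixture(marginalPredictive(model, t_past))
  reps <- sampleGMM(marg_past, n_sim)$x
  G_ref <- vapply(seq_len(n_sim), function(s) klStat(reps[s, ])[1], numeric(1))
  p <- (1 + sum(G_ref >= obs[1])) / (1 + n_sim)
  list(p = p, G_obs = obs[1], G_obs_se = obs[2], G_ref = G_ref)
}
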