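#' Prediction-accuracy and density-forecast metrics
#'
#' Per-subject RMSE of the predictive mean over that subject's held-out
#' points; the replication-level log-RMSE is the natural log of the
#' subject-averaged RMSE. The negative log-score is the subject average of
#' minus the log predictive density of the held-out data (a proper scoring
#' rule; pass the marginal-likelihood values when nothing is conditioned on).
#'
#' @param pred_means list of per-subject predicted-mean vectors.
#' @param truths list of per-subject held-out truth vectors (same shapes).
#' @param logdens optional numeric vector of per-subject log predictive
#'   densities of the held-out data.
#' @return list with \code{rmse} (per subject), \code{mean_rmse},
#'   \code{log_rmse} (NA with \code{degenerate = TRUE} when the mean RMSE is
#'   exactly zero), and \code{neg_log_score} (NULL unless logdens given).
#' @export
predictionMetrics <- function(pred_means, truths, logdens = NULL) {
  stopifnot(length(pred_means) == length(truths))
  if (!length(truths) || any(lengths(truths) == 0L))
    stop("empty held-out set")
  rmse <- vapply(seq_along(truths), function(i) {
    stopifnot(length(pred_means[[i]]) == length(truths[[i]]))
    sqrt(mean((pred_means[[i]] - truths[[i]])^2))
  }, numeric(1))
  mr <- mean(rmse)
  degenerate <- mr == 0
  list(rmse = rmse, mean_rmse = mr,
       log_rmse = if (degenerate) NA_real_ else log(mr),
       degenerate = degenerate,
       neg_log_score = if (is.null(logdens)) NULL else mean(-logdens))
}
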