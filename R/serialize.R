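## Versioned JSON-text model files. The file stores the collapsed (pruned)
## Gaussian mixture plus the sigma2 point estimate, basis and architecture --
## everything plug-in prediction needs -- rather than the full variational
## state.

MODEL_SCHEMA_VERSION <- "dmlmm-model-1"

#' Save a fitted model to a versioned JSON text file
#'
#' @param model a \linkS4class{DMLMMFit}.
#' @param path output path.
#' @export
writeDMLMM <- function(model, path) {
  stopifnot(is(model, "DMLMMFit"))
  b <- model@basis
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    basis = list(kind = b@kind, d = b@d, domain = b@domain, period = b@period,
                 nSeasonal = b@nSeasonal, nTrend = b@nTrend),
    architecture = list(D = model@architecture@D, K = model@architecture@K),
    gmm = list(weights = model@gmm@weights,
               means = model@gmm@means,
               covariances = lapply(seq_along(model@gmm@weights), function(k) {
                 S <- model@gmm@covariances[, , k]
                 if (!is.matrix(S)) S <- matrix(S, nrow(model@gmm@means), nrow(model@gmm@means))
                 S
               }),
               pathLabels = model@gmm@pathLabels),
    sigma2 = model@sigma2,
    seed = model@seed,
    elboTrace = model@elboTrace)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, na = "string")
  writeLines(json, path)
  invisible(path)
}

#' Load a fitted model from a JSON text file
#'
#' @param path model file written by \code{writeDMLMM}.
#' @return a \linkS4class{DMLMMFit}.
#' @export
readDMLMM <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e) stop("parse error reading model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) || !identical(obj$schema_version, MODEL_SCHEMA_VERSION))
    stop("unsupported model file version: ",
         obj$schema_version %||% "<missing>", " (expected ", MODEL_SCHEMA_VERSION, ")")
  b <- obj$basis
  basis <- new("BasisSpec", kind = b$kind, d = as.integer(b$d),
               domain = as.numeric(b$domain),
               period = if (is.null(b$period) || is.character(b$period)) NA_real_ else as.numeric(b$period),
               nSeasonal = as.integer(b$nSeasonal), nTrend = as.integer(b$nTrend))
  arch <- dmfaArchitecture(obj$architecture$D, obj$architecture$K)
  K <- length(obj$gmm$weights)
  d <- basis@d
  covs <- array(0, c(d, d, K))
  rawcov <- obj$gmm$covariances
  for (k in seq_len(K)) {
    covs[, , k] <- if (is.list(rawcov)) matrix(unlist(rawcov[[k]]), d, d,
                                               byrow = FALSE)
    else matrix(rawcov[k, , ], d, d)
  }
  pl <- obj$gmm$pathLabels
  if (is.null(dim(pl))) pl <- matrix(pl, nrow = K)
  storage.mode(pl) <- "integer"
  gmm <- new("GaussianMixture", weights = as.numeric(obj$gmm$weights),
             means = matrix(as.numeric(obj$gmm$means), d, K),
             covariances = covs, pathLabels = pl)
  tr <- obj$elboTrace
  if (is.null(tr) || !length(tr)) tr <- matrix(numeric(0), 0, 2)
  else if (is.null(dim(tr))) tr <- matrix(tr, ncol = 2)
  new("DMLMMFit", gmm = gmm, sigma2 = as.numeric(obj$sigma2), basis = basis,
      architecture = arch, elboTrace = tr,
      responsibilities = matrix(numeric(0), 0, K), seed = as.integer(obj$seed))
}
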