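#' Construct a LongitudinalData object
#'
#' @param ids subject identifiers (coerced to character).
#' @param times list of per-subject numeric time vectors.
#' @param values list of per-subject numeric response vectors.
#' @return a \linkS4class{LongitudinalData}.
#' @export
longitudinalData <- function(ids, times, values) {
  new("LongitudinalData", ids = as.character(ids), times = lapply(times, as.numeric),
      values = lapply(values, as.numeric))
}

#' Number of subjects
#' @param x a LongitudinalData.
#' @export
nSubjects <- function(x) length(x@ids)

#' Subject identifiers
#' @param x a LongitudinalData.
#' @export
subjectIds <- function(x) x@ids

#' Per-subject observation counts n_i
#' @param x a LongitudinalData.
#' @export
obsCounts <- function(x) lengths(x@times)

#' Per-subject time vectors
#' @param x a LongitudinalData.
#' @export
subjectTimes <- function(x) x@times

#' Per-subject response vectors
#' @param x a LongitudinalData.
#' @export
subjectValues <- function(x) x@values

#' Read long-format longitudinal data from CSV
#'
#' One row per observation; rows are grouped by subject id (within-subject
#' order follows file order). Subjects whose responses are all missing are
#' rejected; individual missing response cells are dropped with their rows.
#'
#' @param path CSV file with a header row.
#' @param id_col,time_col,value_col column names.
#' @return a \linkS4class{LongitudinalData}.
#' @export
readLongCSV <- function(path, id_col = "id", time_col = "time", value_col = "value") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: no data rows in ", path)
  for (cn in c(id_col, time_col, value_col)) {
    if (!cn %in% names(df)) stop("configuration error: missing column '", cn, "' in ", path)
  }
  tt <- df[[time_col]]; vv <- df[[value_col]]
  if (!is.numeric(tt)) {
    tn <- suppressWarnings(as.numeric(tt))
    bad <- which(is.na(tn) & !is.na(tt) & nzchar(tt))
    if (length(bad)) stop("parse error: non-numeric time at data row ", bad[1])
    tt <- tn
  }
  if (!is.numeric(vv)) {
    vn <- suppressWarnings(as.numeric(vv))
    bad <- which(is.na(vn) & !is.na(vv) & nzchar(vv))
    if (length(bad)) stop("parse error: non-numeric value at data row ", bad[1])
    vv <- vn
  }
  if (any(is.na(tt))) stop("parse error: missing time at data row ", which(is.na(tt))[1])
  ids <- as.character(df[[id_col]])
  keep <- !is.na(vv)
  uid <- unique(ids)
  dropped <- setdiff(uid, unique(ids[keep]))
  if (length(dropped))
    stop("subject(s) with all responses missing: ", paste(dropped, collapse = ", "))
  ids <- ids[keep]; tt <- tt[keep]; vv <- vv[keep]
  longitudinalData(uid, split(tt, factor(ids, levels = uid)),
                   split(vv, factor(ids, levels = uid)))
}

#' Write long-format longitudinal data to CSV
#'
#' @param x a LongitudinalData.
#' @param path output path.
#' @param id_col,time_col,value_col column names to write.
#' @export
writeLongCSV <- function(x, path, id_col = "id", time_col = "time", value_col = "value") {
  ## %.17g guarantees that doubles survive the decimal round trip bit-exactly
  df <- data.frame(
    id = rep(x@ids, lengths(x@times)),
    time = sprintf("%.17g", unlist(x@times, use.names = FALSE)),
    value = sprintf("%.17g", unlist(x@values, use.names = FALSE)),
    stringsAsFactors = FALSE)
  names(df) <- c(id_col, time_col, value_col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert to a long-format data.frame
#' @param x a LongitudinalData.
#' @export
asLongDataFrame <- function(x) {
  data.frame(id = rep(x@ids, lengths(x@times)),
             time = unlist(x@times, use.names = FALSE),
             value = unlist(x@values, use.names = FALSE),
             stringsAsFactors = FALSE)
}
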