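#' @include AllClasses.R
NULL

#' Write / read a recording as an array bundle
#'
#' The bundle is a raw little-endian double array (`<prefix>.bin`,
#' channel-major) plus a JSON sidecar (`<prefix>.json`) carrying the
#' sampling rate, channel names, subject id, group and annotations.
#' The round trip is lossless at double precision.
#'
#' @param rec an [EEGRecording-class].
#' @param prefix path prefix (without extension).
#' @return `writeRecording` returns the prefix invisibly; `readRecording`
#'   returns the recording.
#' @export
writeRecording <- function(rec, prefix) {
  stopifnot(is(rec, "EEGRecording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec@data)), con, size = 8L, endian = "little")
  meta <- list(subject_id = rec@subjectId, group = rec@group, fs = rec@fs,
               channel_names = channelNames(rec),
               n_samples = ncol(rec@data),
               annotations = rec@annotations)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeRecording
#' @param path bundle prefix (as given to `writeRecording`) or an `.edf`
#'   file when `format = "edf"`.
#' @param format `"bundle"` or `"edf"`.
#' @export
readRecording <- function(path, format = c("bundle", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(readEDF(path))
  jf <- paste0(path, ".json"); bf <- paste0(path, ".bin")
  if (!file.exists(jf) || !file.exists(bf))
    stop("array bundle not found at prefix: ", path)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  n_ch <- length(meta$channel_names)
  con <- file(bf, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_ch * meta$n_samples, size = 8L,
                  endian = "little")
  if (length(vals) != n_ch * meta$n_samples)
    stop("array bundle truncated: expected ", n_ch * meta$n_samples,
         " values, got ", length(vals))
  data <- t(matrix(vals, nrow = meta$n_samples, ncol = n_ch))
  rownames(data) <- meta$channel_names
  ann <- meta$annotations
  if (is.null(ann) || length(ann) == 0L) ann <- list()
  if (!is.list(ann)) ann <- as.list(ann)
  EEGRecording(data, fs = meta$fs, subjectId = meta$subject_id,
               group = meta$group, annotations = ann)
}

#' Write / read a FeatureTable as CSV
#'
#' Columns `subject_id` and `label` precede the feature columns; the header
#' row carries the `"<region>__<feature>"` names.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV file path.
#' @export
writeFeatureTable <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  df <- data.frame(subject_id = epochSubjects(ft), label = epochLabels(ft),
                   featureMatrix(ft), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("subject_id", "label") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")), drop = FALSE])
  FeatureTable(vals, labels = df$label, subjectIds = df$subject_id)
}

#' Write / read a SelectionResult as CSV
#'
#' @param sel a [SelectionResult-class].
#' @param path CSV file path.
#' @export
writeSelectionResult <- function(sel, path) {
  stopifnot(is(sel, "SelectionResult"))
  df <- sel@stats
  attr(df, "alpha") <- NULL
  write.csv(cbind(df, alpha = sel@alpha, gate_alpha = sel@gateAlpha,
                  adjust = sel@adjust, n_tested = sel@nTested),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelectionResult
#' @export
readSelectionResult <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  new("SelectionResult",
      stats = df[, setdiff(names(df), c("alpha", "gate_alpha", "adjust", "n_tested"))],
      alpha = df$alpha[1L], gateAlpha = df$gate_alpha[1L],
      adjust = as.character(df$adjust[1L]), nTested = as.integer(df$n_tested[1L]))
}

#' Write / read an EvalReport as JSON
#'
#' @param report an [EvalReport-class].
#' @param path JSON file path.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  jsonlite::write_json(
    list(k = report@k, grouping = report@grouping, seed = report@seed,
         metrics = report@metrics, folds = report@folds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EvalReport", metrics = as.data.frame(x$metrics),
      folds = if (is.null(x$folds)) list() else as.list(x$folds),
      k = as.integer(x$k), grouping = x$grouping, seed = as.integer(x$seed))
}
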