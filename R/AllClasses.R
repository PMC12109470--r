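#' @include eegstack-package.R
NULL

.GROUPS <- c("MDD", "HC", "unknown")

#' Continuous multichannel EEG recording
#'
#' Holds a channels-by-samples matrix in microvolts together with the
#' sampling rate, subject identity and group label. Channel names live in
#' the rownames of `data`.
#'
#' @slot subjectId single string identifying the subject.
#' @slot group one of `"MDD"`, `"HC"`, `"unknown"` (MDD is the positive class).
#' @slot fs sampling rate in samples per second.
#' @slot data numeric matrix, channels x samples, microvolts; rownames are
#'   channel names in 10-20 nomenclature.
#' @slot annotations free-form named list (provenance, blink onsets, ...).
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    subjectId   = "character",
    group       = "character",
    fs          = "numeric",
    data        = "matrix",
    annotations = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (!(object@group %in% .GROUPS))
    msg <- c(msg, sprintf("group must be one of %s", paste(.GROUPS, collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must carry channel names as rownames")
  if (anyDuplicated(rownames(object@data)))
    msg <- c(msg, "duplicated channel names")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts) with channel
#'   names as rownames, or without rownames if `channelNames` is given.
#' @param fs sampling rate (Hz).
#' @param subjectId subject identifier.
#' @param group `"MDD"`, `"HC"` or `"unknown"`.
#' @param channelNames optional channel names (length `nrow(data)`).
#' @param annotations named list of free-form metadata.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), 2, 256,
#'   dimnames = list(c("Fp1", "Fp2"), NULL)), fs = 256)
#' nSamples(rec)
#' @export
EEGRecording <- function(data, fs, subjectId = "S01", group = "unknown",
                         channelNames = NULL, annotations = list()) {
  data <- as.matrix(data)
  if (!is.null(channelNames)) rownames(data) <- channelNames
  new("EEGRecording", subjectId = as.character(subjectId), group = group,
      fs = as.numeric(fs), data = data, annotations = annotations)
}

#' Set of fixed-length epochs cut from one recording
#'
#' @slot epochs numeric array, epochs x channels x samples (microvolts).
#' @slot fs sampling rate (Hz).
#' @slot windowSeconds epoch length (s).
#' @slot overlapSeconds overlap between adjacent epochs (s).
#' @slot startSeconds onset of each epoch relative to the (cropped)
#'   recording start (s).
#' @slot retained logical, one flag per epoch (quality control result).
#' @slot subjectId,group provenance copied from the source recording.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs         = "array",
    fs             = "numeric",
    windowSeconds  = "numeric",
    overlapSeconds = "numeric",
    startSeconds   = "numeric",
    retained       = "logical",
    subjectId      = "character",
    group          = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  if (length(object@retained) != d[1L])
    msg <- c(msg, "retained mask length must equal epoch count")
  if (length(object@startSeconds) != d[1L])
    msg <- c(msg, "startSeconds length must equal epoch count")
  expected <- round(object@windowSeconds * object@fs)
  if (length(d) == 3L && d[3L] != expected)
    msg <- c(msg, sprintf("samples per epoch (%d) must equal round(windowSeconds * fs) = %d",
                          d[3L], expected))
  if (length(msg)) msg else TRUE
})

#' Epoch-by-feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `"features"` holds features (rows) by epochs (columns); `colData` carries
#' `subject_id` and `group` per epoch. Feature names follow the
#' `"<region>__<feature>"` convention; with the default region map and full
#' schema there are exactly 95 of them.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

#' Construct a FeatureTable
#'
#' @param values epochs x features numeric matrix with column names
#'   `"<region>__<feature>"`.
#' @param labels group label per row (`"MDD"`/`"HC"`).
#' @param subjectIds subject id per row.
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(values, labels, subjectIds) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("feature values must carry column names")
  if (anyNA(values)) stop("FeatureTable must not contain NA values")
  stopifnot(length(labels) == nrow(values), length(subjectIds) == nrow(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(features = t(values)),
    colData = S4Vectors::DataFrame(subject_id = as.character(subjectIds),
                                   group      = as.character(labels))
  )
  new("FeatureTable", se)
}

#' Per-feature selection decisions
#'
#' @slot stats data.frame with one row per feature: the gate-test p-values,
#'   the routed test, raw and adjusted p-values and the selected flag.
#' @slot alpha significance level applied to adjusted p-values.
#' @slot gateAlpha level used by the Shapiro-Wilk / Levene routing gates.
#' @slot adjust multiplicity adjustment used (`"bonferroni"` or `"BH"`).
#' @slot nTested number of features in the adjustment family.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(stats = "data.frame", alpha = "numeric",
                 gateAlpha = "numeric", adjust = "character",
                 nTested = "integer")
)

#' Cross-validation evaluation report
#'
#' @slot metrics data.frame, one row per model (or per region for ablation
#'   reports): pooled confusion counts, accuracy, recall, F1, AUC from
#'   pooled scores and mean per-fold AUC.
#' @slot folds list of per-model fold-level detail.
#' @slot k number of folds.
#' @slot grouping `"subject"` or `"epoch"`.
#' @slot seed fold-assignment seed.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(metrics = "data.frame", folds = "list", k = "integer",
                 grouping = "character", seed = "integer")
)
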