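#' @include AllClasses.R
NULL

#' Accessors for eegstack objects
#'
#' Channel names, sample counts, durations, group labels and feature
#' matrices of the core classes.
#'
#' @param x an [EEGRecording-class], [EpochSet-class] or [FeatureTable-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) dimnames(x@epochs)[[2L]])

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("groupLabel", "EEGRecording", function(x) x@group)

#' @rdname accessors
#' @export
setMethod("groupLabel", "EpochSet", function(x) x@group)

#' @rdname accessors
#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("retainedMask", "EpochSet", function(x) x@retained)

#' Epoch data array of an EpochSet
#' @param x an [EpochSet-class].
#' @param retainedOnly drop epochs flagged by quality control?
#' @return epochs x channels x samples array.
#' @export
epochArray <- function(x, retainedOnly = FALSE) {
  stopifnot(is(x, "EpochSet"))
  if (retainedOnly) x@epochs[x@retained, , , drop = FALSE] else x@epochs
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' Epoch labels / subject ids of a FeatureTable
#' @param x a [FeatureTable-class].
#' @return character vector, one entry per epoch row.
#' @export
epochLabels <- function(x) as.character(SummarizedExperiment::colData(x)$group)

#' @rdname epochLabels
#' @export
epochSubjects <- function(x) as.character(SummarizedExperiment::colData(x)$subject_id)

#' Selection statistics table
#' @param x a [SelectionResult-class].
#' @return data.frame with one row per feature.
#' @export
selectionStats <- function(x) { stopifnot(is(x, "SelectionResult")); x@stats }

#' Names of selected features
#' @param x a [SelectionResult-class].
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@stats$feature[x@stats$selected]
}

#' Evaluation metrics table
#' @param x an [EvalReport-class].
#' @return data.frame with one row per model.
#' @export
reportMetrics <- function(x) { stopifnot(is(x, "EvalReport")); x@metrics }

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s' (%s): %d epochs (%d retained) x %d channels x %d samples, window %gs overlap %gs\n",
              object@subjectId, object@group, d[1L], sum(object@retained),
              d[2L], d[3L], object@windowSeconds, object@overlapSeconds))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features tested (%s, alpha=%g), %d selected\n",
              object@nTested, object@adjust, object@alpha,
              sum(object@stats$selected)))
  n <- table(object@stats$test_used)
  cat(sprintf("  routing: %s\n",
              paste(sprintf("%s=%d", names(n), n), collapse = ", ")))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d-fold CV (%s grouping, seed %d)\n",
              object@k, object@grouping, object@seed))
  print(object@metrics, digits = 4)
})
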