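#' @include AllClasses.R synthetic.R preprocess.R segment.R features.R
#' @include selection.R crossval.R ablation.R bandreport.R io.R
NULL

#' End-to-end pipeline configuration
#'
#' Bundles all stage parameters with a master seed. Defaults mirror the
#' reference protocol: 0.5-50 Hz band-pass with a 50 Hz notch, ICA blink
#' suppression at |r| >= 0.7, crop to 30-155 s, 32 s epochs with 1 s
#' overlap, 100 uV reject / 1 uV flat QC, the standard band scheme and
#' 5-region map, Bonferroni selection at alpha 0.05 and subject-grouped
#' 5-fold CV of the stacking ensemble.
#'
#' @param cohort a [cohortSpec()] (to simulate) or `NULL` when
#'   `inputDir` points at saved recording bundles.
#' @param inputDir directory of array bundles (one prefix per subject) as
#'   written by [writeRecording()]; used when `cohort` is `NULL`.
#' @param low,high,notch filter settings, Hz.
#' @param icaThreshold ICA artifact-correlation threshold; `NA` skips ICA.
#' @param tStart,tEnd crop window, s.
#' @param window,overlap epoch geometry, s.
#' @param reject,flat QC thresholds, uV.
#' @param bands a [bandScheme()].
#' @param regions a region map.
#' @param featParams a [featureParams()] list.
#' @param alpha selection level.
#' @param models named list of model specs for [crossValidate()].
#' @param k CV folds (>= 2).
#' @param grouping `"subject"` or `"epoch"`.
#' @param seed master seed.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(cohort = cohortSpec(), inputDir = NULL,
                           low = 0.5, high = 50, notch = 50,
                           icaThreshold = 0.7, tStart = 30, tEnd = 155,
                           window = 32, overlap = 1, reject = 100, flat = 1,
                           bands = bandScheme("standard"),
                           regions = defaultRegionMap(),
                           featParams = featureParams(), alpha = 0.05,
                           models = list(stacking = stackingSpec()),
                           k = 5L, grouping = c("subject", "epoch"),
                           seed = 1L) {
  grouping <- match.arg(grouping)
  if (is.null(cohort) && is.null(inputDir))
    stop("either a cohort spec or an input directory is required")
  if (k < 2L) stop("k must be at least 2")
  if (overlap >= window) stop("overlap must be smaller than window")
  if (tEnd - tStart < window) stop("crop window shorter than one epoch")
  .validateBandScheme(bands); .validateRegionMap(regions)
  structure(list(cohort = cohort, inputDir = inputDir, low = low,
                 high = high, notch = notch, icaThreshold = icaThreshold,
                 tStart = tStart, tEnd = tEnd, window = window,
                 overlap = overlap, reject = reject, flat = flat,
                 bands = bands, regions = regions, featParams = featParams,
                 alpha = alpha, models = models, k = as.integer(k),
                 grouping = grouping, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.loadOrSimulate <- function(config) {
  if (!is.null(config$cohort)) return(generateCohort(config$cohort))
  prefixes <- unique(sub("\\.(bin|json)$", "",
                         list.files(config$inputDir,
                                    pattern = "\\.(bin|json)$",
                                    full.names = TRUE)))
  if (!length(prefixes)) stop("no recording bundles found in ", config$inputDir)
  lapply(sort(prefixes), readRecording)
}

#' Run the full pipeline
#'
#' Stages in order: simulate (or ingest) -> preprocess (average reference,
#' filter, optional ICA) -> crop/segment/QC -> feature table -> selection
#' -> cross-validated models -> band-power report. When `outDir` is given,
#' features, selection results, the reduced table, the CV report and a
#' provenance sidecar (seed, stage parameters, row/epoch/feature counts)
#' are written there; a rerun with the same config reproduces them.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory.
#' @param verbose print stage-level progress?
#' @return list: `features` ([FeatureTable-class]), `selection`,
#'   `reduced`, `regionShares`, `report` ([EvalReport-class]),
#'   `bandReport`, `counts` (stage-level bookkeeping).
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  recs <- .loadOrSimulate(config)
  say("ingest: %d recordings", length(recs))
  epochSets <- lapply(recs, function(rec) {
    rec <- applyAverageReference(rec)
    rec <- filterRecording(rec, config$low, config$high, config$notch)
    if (!is.na(config$icaThreshold))
      rec <- removeArtifactComponents(rec, config$icaThreshold,
                                      seed = config$seed)$recording
    rec <- cropRecording(rec, config$tStart, config$tEnd)
    qcEpochs(epochRecording(rec, config$window, config$overlap),
             config$reject, config$flat)
  })
  nRetained <- sum(vapply(epochSets, function(e) sum(retainedMask(e)), 0L))
  say("segment: %d retained epochs", nRetained)
  if (nRetained == 0L) stop("stage segment: no epochs survived quality control")
  ft <- buildFeatureTable(epochSets, config$regions, config$bands,
                          config$featParams)
  say("features: %d epochs x %d features", ncol(ft), nrow(ft))
  sel <- selectFeatures(ft, alpha = config$alpha)
  nSel <- sum(selectionStats(sel$result)$selected)
  say("selection: %d -> %d features", nrow(ft), nSel)
  useTable <- if (nSel > 0L) sel$reduced else ft
  report <- crossValidate(useTable, config$models, config$k,
                          config$grouping, config$seed)
  bandRep <- bandPowerGroupReport(ft)
  counts <- list(n_subjects = length(recs), n_retained_epochs = nRetained,
                 n_features = nrow(ft), n_selected = nSel,
                 selection_fallback_all_features = nSel == 0L)
  out <- list(features = ft, selection = sel$result, reduced = sel$reduced,
              regionShares = sel$regionShares, report = report,
              bandReport = bandRep, counts = counts)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(ft, file.path(outDir, "features.csv"))
    writeSelectionResult(sel$result, file.path(outDir, "selection.csv"))
    writeFeatureTable(useTable, file.path(outDir, "reduced.csv"))
    writeEvalReport(report, file.path(outDir, "cv_report.json"))
    jsonlite::write_json(
      list(seed = config$seed, counts = counts,
           params = list(low = config$low, high = config$high,
                         notch = config$notch, ica = config$icaThreshold,
                         crop = c(config$tStart, config$tEnd),
                         window = config$window, overlap = config$overlap,
                         reject = config$reject, flat = config$flat,
                         alpha = config$alpha, k = config$k,
                         grouping = config$grouping)),
      file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the per-region ablation from a pipeline config
#'
#' Produces the full feature table (via [runPipeline()] stages, or reuses
#' a supplied one) and delegates to [regionAblation()].
#'
#' @param config a [pipelineConfig()].
#' @param ft optional precomputed [FeatureTable-class]; skips the
#'   simulation and feature stages.
#' @param spec the [stackingSpec()] evaluated per region.
#' @param outDir optional directory for the per-region CSV.
#' @return an [EvalReport-class] with one row per region.
#' @export
runRegionAblation <- function(config, ft = NULL, spec = stackingSpec(),
                              outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(ft)) {
    if (is.null(config$cohort) && is.null(config$inputDir))
      stop("no feature table given and no cohort spec or input directory ",
           "to produce one from")
    ft <- runPipeline(config)$features
  }
  rep <- regionAblation(ft, config$regions, spec, k = config$k,
                        grouping = config$grouping, seed = config$seed,
                        alpha = config$alpha)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(reportMetrics(rep), file.path(outDir, "region_ablation.csv"),
              row.names = FALSE)
  }
  rep
}
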