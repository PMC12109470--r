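#' @include AllClasses.R crossval.R selection.R
NULL

#' Per-region ablation of the stacking pipeline
#'
#' For each region, the feature table is restricted to that region's
#' columns, feature selection is rerun inside the subset (the Bonferroni
#' family is the region's feature count), and the stacking ensemble is
#' cross-validated on the surviving features. Regions are ranked by
#' accuracy. A region in which no feature survives selection is evaluated
#' on its unselected raw features and flagged.
#'
#' @param ft the full [FeatureTable-class].
#' @param regions region map (default [defaultRegionMap()]).
#' @param spec a [stackingSpec()].
#' @param k,grouping,seed cross-validation settings (see [crossValidate()]).
#' @param alpha selection level within each region.
#' @return an [EvalReport-class] whose metrics carry one row per region
#'   (columns `region`, `n_selected`, `no_feature_flag`, metrics), ranked
#'   by accuracy.
#' @export
regionAblation <- function(ft, regions = defaultRegionMap(),
                           spec = stackingSpec(), k = 5L,
                           grouping = c("subject", "epoch"), seed = 1L,
                           alpha = 0.05) {
  grouping <- match.arg(grouping)
  stopifnot(is(ft, "FeatureTable"))
  .validateRegionMap(regions)
  allCols <- rownames(ft)
  rows <- list(); folds <- list()
  for (r in names(regions)) {
    cols <- allCols[startsWith(allCols, paste0(r, "__"))]
    if (!length(cols)) stop("feature table has no columns for region ", r)
    sub <- ft[match(cols, allCols), ]
    sel <- selectFeatures(sub, alpha = alpha)
    noFeature <- nrow(sel$reduced) == 0L
    use <- if (noFeature) sub else sel$reduced
    rep <- crossValidate(use, list(stacking = spec), k = k,
                         grouping = grouping, seed = seed)
    m <- rep@metrics
    m$model <- NULL
    rows[[r]] <- cbind(data.frame(region = r,
                                  n_selected = sum(selectionStats(sel$result)$selected),
                                  no_feature_flag = noFeature), m)
    folds[[r]] <- rep@folds$stacking
  }
  metrics <- do.call(rbind, rows)
  metrics <- metrics[order(-metrics$accuracy), ]
  rownames(metrics) <- NULL
  new("EvalReport", metrics = metrics, folds = folds, k = as.integer(k),
      grouping = grouping, seed = as.integer(seed))
}
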