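#' @include AllClasses.R learners.R stacking.R metrics.R
NULL

#' Cross-validation fold assignment
#'
#' Epoch grouping: stratified assignment of rows so fold sizes differ by
#' at most one per class. Subject grouping: whole subjects are assigned to
#' folds (stratified by the subject's group label), so no subject's epochs
#' span folds. Deterministic given `seed`.
#'
#' @param labels row labels (`"MDD"`/`"HC"` or 0/1).
#' @param subjects subject id per row (used for `grouping = "subject"`).
#' @param k number of folds.
#' @param grouping `"subject"` (default) or `"epoch"`.
#' @param seed shuffle seed.
#' @return integer fold index per row.
#' @export
makeFolds <- function(labels, subjects, k = 5L, grouping = c("subject", "epoch"),
                      seed = 1L) {
  grouping <- match.arg(grouping)
  y <- .asBinaryLabel(labels)
  if (k < 2L) stop("k must be at least 2")
  if (grouping == "epoch") {
    fold <- .stratifiedFolds(y, k, seed)
  } else {
    stopifnot(length(subjects) == length(y))
    subLab <- vapply(split(y, subjects), `[`, 0L, 1L)
    subFold <- setNames(integer(length(subLab)), names(subLab))
    withr::with_seed(as.integer(seed), {
      for (cl in unique(subLab)) {
        s <- sample(names(subLab)[subLab == cl])
        subFold[s] <- rep_len(seq_len(k), length(s))
      }
    })
    fold <- subFold[as.character(subjects)]
  }
  for (f in seq_len(k))
    if (length(unique(y[fold == f])) < 2L)
      stop("fold ", f, " contains a single class; stratification failed ",
           "(too few rows or subjects per class for k = ", k, ")")
  unname(fold)
}

.evalFold <- function(scores, yTest) {
  lab <- as.integer(scores >= 0.5)
  c(tp = sum(lab == 1L & yTest == 1L), fp = sum(lab == 1L & yTest == 0L),
    tn = sum(lab == 0L & yTest == 0L), fn = sum(lab == 0L & yTest == 1L))
}

#' Cross-validated evaluation of baseline learners and stacking
#'
#' Runs stratified k-fold cross-validation (subject-grouped by default, so
#' epochs of one subject never appear in both train and test) for each
#' model, accumulating per-fold confusion counts and scores. Accuracy,
#' recall and F1 come from the pooled confusion counts; AUC is computed
#' from the pooled scores, with the mean of per-fold AUCs also reported.
#'
#' @param ft a [FeatureTable-class].
#' @param models named list of [learnerSpec()] and/or [stackingSpec()]
#'   objects.
#' @param k number of folds (default 5).
#' @param grouping `"subject"` (default) or `"epoch"`.
#' @param seed fold-assignment seed.
#' @return an [EvalReport-class].
#' @export
crossValidate <- function(ft, models = list(stacking = stackingSpec()),
                          k = 5L, grouping = c("subject", "epoch"),
                          seed = 1L) {
  grouping <- match.arg(grouping)
  stopifnot(is(ft, "FeatureTable"), length(models) >= 1L)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  X <- featureMatrix(ft)
  y <- .asBinaryLabel(epochLabels(ft))
  fold <- makeFolds(epochLabels(ft), epochSubjects(ft), k, grouping, seed)
  rows <- list(); folds <- list()
  for (mn in names(models)) {
    spec <- models[[mn]]
    counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    allScores <- numeric(nrow(X)); foldAuc <- numeric(0)
    foldAcc <- numeric(0)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      scores <- if (inherits(spec, "StackingSpec")) {
        m <- fitStacking(X[tr, , drop = FALSE], y[tr], spec)
        predictStacking(m, X[te, , drop = FALSE])$score
      } else {
        m <- .fitLearner(spec, X[tr, , drop = FALSE], y[tr])
        .predictLearner(m, X[te, , drop = FALSE])
      }
      cm <- .evalFold(scores, y[te])
      counts <- counts + cm
      allScores[te] <- scores
      foldAuc <- c(foldAuc, rocAuc(scores, y[te]))
      foldAcc <- c(foldAcc, (cm["tp"] + cm["tn"]) / sum(cm))
    }
    met <- confusionMetrics(counts["tp"], counts["fp"], counts["tn"], counts["fn"])
    rows[[mn]] <- data.frame(
      model = mn, accuracy = met["accuracy"], recall = met["recall"],
      f1 = met["f1"], auc = rocAuc(allScores, y),
      auc_mean_folds = mean(foldAuc),
      TP = counts["tp"], FP = counts["fp"], TN = counts["tn"],
      FN = counts["fn"], row.names = NULL)
    folds[[mn]] <- list(auc = foldAuc, accuracy = unname(foldAcc))
  }
  new("EvalReport", metrics = do.call(rbind, rows), folds = folds,
      k = as.integer(k), grouping = grouping, seed = as.integer(seed))
}

#' The eight baseline learner specifications
#'
#' @param seed seed shared by the stochastic learners.
#' @param includeUnavailable also list kinds whose backing package is not
#'   installed (they error at fit time)?
#' @return named list of [learnerSpec()] objects.
#' @export
baselineLearners <- function(seed = 1L, includeUnavailable = FALSE) {
  kinds <- .LEARNER_KINDS
  if (!includeUnavailable && !requireNamespace("lightgbm", quietly = TRUE))
    kinds <- setdiff(kinds, "lgbm")
  setNames(lapply(kinds, learnerSpec, seed = seed), kinds)
}
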