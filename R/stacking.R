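#' @include AllClasses.R learners.R
NULL

#' Specify the stacking ensemble
#'
#' Defaults mirror the tuned ensemble of the reference analysis: base
#' learners kNN (k = 5), decision tree (depth 5) and gradient boosting
#' (learning rate 0.01, depth 3, 100 rounds), a decision-tree
#' meta-learner, and passthrough of the original features alongside the
#' base learners' out-of-fold scores.
#'
#' @param base list of [learnerSpec()] objects.
#' @param meta a [learnerSpec()] for the meta-learner.
#' @param passthrough concatenate the original features to the base scores
#'   when training and applying the meta-learner? (default `TRUE`).
#' @param oofFolds internal folds used to generate out-of-fold base scores
#'   for meta training (default 5).
#' @param seed seed controlling the internal fold assignment.
#' @return a list of class `"StackingSpec"`.
#' @export
stackingSpec <- function(base = list(
                           learnerSpec("knn", list(n_neighbors = 5L)),
                           learnerSpec("dt", list(max_depth = 5L)),
                           learnerSpec("xgboost", list(learning_rate = 0.01,
                                                       max_depth = 3L,
                                                       n_estimators = 100L))),
                         meta = learnerSpec("dt", list(max_depth = 5L)),
                         passthrough = TRUE, oofFolds = 5L, seed = 1L) {
  stopifnot(length(base) >= 1L,
            all(vapply(base, inherits, TRUE, "LearnerSpec")),
            inherits(meta, "LearnerSpec"))
  structure(list(base = base, meta = meta, passthrough = passthrough,
                 oofFolds = as.integer(oofFolds), seed = as.integer(seed)),
            class = "StackingSpec")
}

# Stratified fold assignment of binary labels, deterministic given seed.
.stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

.baseName <- function(spec, i) paste0("base_", i, "_", spec$kind)

#' Fit the stacking ensemble
#'
#' Base learners produce out-of-fold positive-class scores on the training
#' rows (internal stratified folds); the meta-features are those score
#' columns, concatenated with the original features when passthrough is
#' on; the meta-learner is fitted on them; finally the base learners are
#' refitted on the full training data for inference. Deterministic given
#' the spec's seed.
#'
#' @param X training feature matrix (rows x features, named columns).
#' @param y binary labels (1 = MDD) or `"MDD"/"HC"` character labels.
#' @param spec a [stackingSpec()].
#' @return an object of class `"StackingModel"`.
#' @export
fitStacking <- function(X, y, spec = stackingSpec()) {
  X <- as.matrix(X)
  y <- .asBinaryLabel(y)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (nrow(X) < 2L * spec$oofFolds)
    stop("need at least 2 rows per internal fold")
  fold <- .stratifiedFolds(y, spec$oofFolds, spec$seed)
  oof <- matrix(NA_real_, nrow(X), length(spec$base))
  colnames(oof) <- vapply(seq_along(spec$base), function(i)
    .baseName(spec$base[[i]], i), "")
  for (f in seq_len(spec$oofFolds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (length(unique(y[tr])) < 2L)
      stop("internal stacking fold lost a class; use fewer folds")
    for (i in seq_along(spec$base)) {
      m <- .fitLearner(spec$base[[i]], X[tr, , drop = FALSE], y[tr])
      oof[te, i] <- .predictLearner(m, X[te, , drop = FALSE])
    }
  }
  metaX <- if (spec$passthrough) cbind(oof, X) else oof
  meta <- .fitLearner(spec$meta, metaX, y)
  bases <- lapply(spec$base, function(s) .fitLearner(s, X, y))
  structure(list(spec = spec, meta = meta, bases = bases,
                 columns = colnames(X), metaWidth = ncol(metaX)),
            class = "StackingModel")
}

.asBinaryLabel <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "MDD")
  else as.integer(y)
}

#' @export
print.StackingModel <- function(x, ...) {
  cat(sprintf("StackingModel: %d base learners (%s), meta %s, passthrough %s, meta-feature width %d\n",
              length(x$bases),
              paste(vapply(x$bases, `[[`, "", "kind"), collapse = "+"),
              x$meta$kind, x$spec$passthrough, x$metaWidth))
  invisible(x)
}

#' Score new rows with a fitted stacking ensemble
#'
#' @param model a `"StackingModel"` from [fitStacking()].
#' @param X feature matrix whose columns match the training columns.
#' @return data.frame with `score` (positive-class probability) and
#'   `label` (`1` when score >= 0.5).
#' @export
predictStacking <- function(model, X) {
  stopifnot(inherits(model, "StackingModel"))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !identical(colnames(X), model$columns)) {
    miss <- setdiff(model$columns, colnames(X))
    extra <- setdiff(colnames(X), model$columns)
    if (length(miss) || length(extra))
      stop("columns do not match training columns",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
    X <- X[, model$columns, drop = FALSE]
  }
  scores <- vapply(model$bases, function(b) .predictLearner(b, X),
                   numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- vapply(seq_along(model$bases), function(i)
    .baseName(model$spec$base[[i]], i), "")
  metaX <- if (model$spec$passthrough) cbind(scores, X) else scores
  s <- .predictLearner(model$meta, metaX)
  data.frame(score = s, label = as.integer(s >= 0.5))
}
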