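#' @include AllClasses.R
NULL

.LEARNER_KINDS <- c("dt", "knn", "rf", "svm", "lgbm", "xgboost", "gb", "nn")

.learnerDefaults <- function(kind) {
  switch(kind,
    dt      = list(max_depth = 20L, min_samples_split = 10L),
    knn     = list(n_neighbors = 5L, weights = "distance"),
    rf      = list(max_depth = 10L, n_estimators = 200L),
    svm     = list(C = 1, kernel = "rbf", gamma = "auto"),
    lgbm    = list(learning_rate = 0.1, n_estimators = 500L),
    xgboost = list(learning_rate = 0.05, n_estimators = 1000L, max_depth = 6L),
    gb      = list(learning_rate = 0.1, n_estimators = 200L, max_depth = 3L),
    nn      = list(hidden = 50L, max_iter = 1000L, decay = 1e-4)
  )
}

#' Specify a baseline learner
#'
#' Supported kinds and the backing implementations: `dt` (rpart), `knn`
#' (internal distance-weighted k-nearest-neighbour scorer), `rf`
#' (randomForest), `svm` (e1071, RBF kernel, decision values mapped
#' through a logistic link), `xgboost` and `gb` (xgboost gradient
#' boosting), `nn` (nnet single-hidden-layer perceptron), `lgbm`
#' (requires the lightgbm package). Defaults follow the tuned
#' hyperparameters of the reference analysis.
#'
#' @param kind one of `r paste(.LEARNER_KINDS, collapse = ", ")`.
#' @param params named list overriding the kind's defaults.
#' @param seed integer seed used by stochastic learners.
#' @return a list of class `"LearnerSpec"`.
#' @export
learnerSpec <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, .LEARNER_KINDS)
  structure(list(kind = kind,
                 params = modifyList(.learnerDefaults(kind), params),
                 seed = as.integer(seed)),
            class = "LearnerSpec")
}

# Column-standardize a matrix (constant columns left centered only).
.fitScaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.applyScaler <- function(sc, X) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

# Fit one learner on X (n x p matrix) and binary y (1 = MDD positive).
# Returns an object that .predictLearner() maps to positive-class scores.
.fitLearner <- function(spec, X, y) {
  stopifnot(inherits(spec, "LearnerSpec"))
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  p <- spec$params
  X <- as.matrix(X)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(spec$kind,
    dt = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = min(30L, p$max_depth),
                     minsplit = p$min_samples_split, cp = 0, xval = 0))
    },
    knn = {
      sc <- .fitScaler(X)
      list(X = .applyScaler(sc, X), y = y, k = p$n_neighbors,
           weights = p$weights, scaler = sc)
    },
    rf = withr::with_seed(spec$seed,
      randomForest::randomForest(X, yf, ntree = p$n_estimators,
                                 maxnodes = min(2L^p$max_depth, nrow(X)))),
    svm = {
      m <- e1071::svm(X, yf, cost = p$C, kernel = "radial",
                      gamma = if (identical(p$gamma, "auto")) 1 / ncol(X) else p$gamma,
                      scale = apply(X, 2L, sd) > 0)
      # libsvm orients decision values by training-data class order; pin
      # the orientation so larger score always means the positive class
      dv <- as.vector(attr(predict(m, X, decision.values = TRUE),
                           "decision.values"))
      orient <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
      list(model = m, orient = orient)
    },
    lgbm = {
      if (!requireNamespace("lightgbm", quietly = TRUE))
        stop("learner kind 'lgbm' requires the 'lightgbm' package, ",
             "which is not installed")
      ds <- lightgbm::lgb.Dataset(X, label = y)
      lightgbm::lgb.train(list(objective = "binary",
                               learning_rate = p$learning_rate,
                               seed = spec$seed, verbosity = -1),
                          ds, nrounds = p$n_estimators)
    },
    xgboost = ,
    gb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = p$learning_rate,
                    max_depth = p$max_depth, nthread = 1L, seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = p$n_estimators),
    nn = {
      sc <- .fitScaler(X)
      net <- withr::with_seed(spec$seed,
        nnet::nnet(.applyScaler(sc, X), y, size = p$hidden,
                   maxit = p$max_iter, decay = p$decay, entropy = TRUE,
                   MaxNWts = 100000L, trace = FALSE))
      list(net = net, scaler = sc)
    }
  )
  structure(list(kind = spec$kind, fit = fit, columns = colnames(X)),
            class = "FittedLearner")
}

# Distance-weighted kNN positive-class score.
.knnScore <- function(model, X) {
  tr <- model$X; y <- model$y; k <- model$k
  apply(X, 1L, function(q) {
    d <- sqrt(colSums((t(tr) - q)^2))
    o <- order(d)[seq_len(min(k, length(d)))]
    dn <- d[o]
    if (any(dn == 0)) return(mean(y[o[dn == 0]]))
    w <- if (model$weights == "distance") 1 / dn else rep(1, length(dn))
    sum(w * y[o]) / sum(w)
  })
}

.predictLearner <- function(model, X) {
  stopifnot(inherits(model, "FittedLearner"))
  X <- as.matrix(X)
  if (!is.null(model$columns) && !is.null(colnames(X))) {
    miss <- setdiff(model$columns, colnames(X))
    extra <- setdiff(colnames(X), model$columns)
    if (length(miss) || length(extra))
      stop("feature columns do not match training columns",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
    X <- X[, model$columns, drop = FALSE]
  }
  f <- model$fit
  switch(model$kind,
    dt = predict(f, data.frame(X, check.names = FALSE), type = "prob")[, "1"],
    knn = .knnScore(f, .applyScaler(f$scaler, X)),
    rf = predict(f, X, type = "prob")[, "1"],
    svm = plogis(f$orient *
                 as.vector(attr(predict(f$model, X, decision.values = TRUE),
                                "decision.values"))),
    lgbm = predict(f, X),
    xgboost = ,
    gb = predict(f, xgboost::xgb.DMatrix(X)),
    nn = as.vector(predict(f$net, .applyScaler(f$scaler, X)))
  )
}
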