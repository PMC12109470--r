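# small separable table: one informative dimension plus noise
separableTable <- function(n = 40, p = 6, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] * 0.2 + gap * y
    colnames(X) <- paste0("Frontal__f", seq_len(p))
    FeatureTable(X, labels = ifelse(y == 1, "MDD", "HC"),
                 subjectIds = paste0("S", seq_len(n)))
  })
}

test_that("stacking meta-feature width is bases + passthrough features", {
  ft <- gaussianTable(n = 60, p = 56, seed = 21)
  m <- fitStacking(featureMatrix(ft), epochLabels(ft))
  expect_identical(m$metaWidth, 59L)
  moff <- fitStacking(featureMatrix(ft), epochLabels(ft),
                      stackingSpec(passthrough = FALSE))
  expect_identical(moff$metaWidth, 3L)
})

test_that("stacking separates a separable table and predicts deterministically", {
  ft <- separableTable()
  X <- featureMatrix(ft)
  m <- fitStacking(X, epochLabels(ft))
  pred <- predictStacking(m, X)
  expect_identical(pred$label, eegstack:::.asBinaryLabel(epochLabels(ft)))
  # duplicated row gets an identical score
  X2 <- rbind(X, X[3, , drop = FALSE])
  p2 <- predictStacking(m, X2)
  expect_identical(p2$score[nrow(X2)], p2$score[3])
  # column mismatch errors name the offender
  bad <- X; colnames(bad)[2] <- "Frontal__zzz"
  expect_error(predictStacking(m, bad), "zzz")
  # single-class training errors
  expect_error(fitStacking(X, rep(1, nrow(X))), "single class")
})

test_that("fold assignment is balanced, subject-coherent and deterministic", {
  labs <- rep(c("MDD", "HC"), each = 128)
  subs <- paste0("S", rep(1:64, each = 4))
  f_ep <- makeFolds(labs, subs, k = 5, grouping = "epoch", seed = 3)
  expect_lte(diff(range(table(f_ep))), 2L)
  for (cl in c("MDD", "HC"))
    expect_lte(diff(range(table(f_ep[labs == cl]))), 1L)
  f_su <- makeFolds(labs, subs, k = 5, grouping = "subject", seed = 3)
  expect_true(all(vapply(split(f_su, subs), function(v)
    length(unique(v)) == 1L, logical(1))))
  expect_identical(f_su, makeFolds(labs, subs, k = 5, grouping = "subject",
                                   seed = 3))
  expect_false(identical(f_su, makeFolds(labs, subs, k = 5,
                                         grouping = "subject", seed = 4)))
  expect_error(makeFolds(labs, subs, k = 1), "at least 2")
})

test_that("cross-validation reports coherent metrics for baselines and stacking", {
  ft <- separableTable(n = 60, seed = 5)
  rep <- crossValidate(ft, list(dt = learnerSpec("dt"),
                                knn = learnerSpec("knn"),
                                stacking = stackingSpec()),
                       k = 5, grouping = "epoch", seed = 2)
  m <- reportMetrics(rep)
  expect_identical(nrow(m), 3L)
  expect_true(all(m$accuracy > 0.9))
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_identical(sum(m$TP[1], m$FP[1], m$TN[1], m$FN[1]), 60L)
  # same seed reproduces identical metrics
  rep2 <- crossValidate(ft, list(dt = learnerSpec("dt")), k = 5,
                        grouping = "epoch", seed = 2)
  expect_identical(reportMetrics(rep2)$accuracy,
                   m$accuracy[m$model == "dt"])
})

test_that("every available baseline learner fits and scores", {
  ft <- separableTable(n = 50, seed = 9)
  X <- featureMatrix(ft); y <- eegstack:::.asBinaryLabel(epochLabels(ft))
  specs <- baselineLearners(seed = 2)
  expect_gte(length(specs), 7L)
  for (nm in names(specs)) {
    # full Table-5 sizes are slow for a unit check; shrink the ensembles
    sp <- specs[[nm]]
    if (!is.null(sp$params$n_estimators)) sp$params$n_estimators <- 50L
    if (!is.null(sp$params$max_iter)) sp$params$max_iter <- 200L
    m <- eegstack:::.fitLearner(sp, X, y)
    s <- eegstack:::.predictLearner(m, X)
    expect_length(s, nrow(X))
    expect_true(all(s >= 0 & s <= 1), label = nm)
    expect_gt(rocAuc(s, y), 0.9)
  }
  if (!requireNamespace("lightgbm", quietly = TRUE))
    expect_error(eegstack:::.fitLearner(learnerSpec("lgbm"), X, y), "lightgbm")
})

test_that("a perfect base learner lets stacking reach training accuracy 1", {
  ft <- separableTable(n = 40, gap = 10, seed = 30)
  X <- featureMatrix(ft); y <- epochLabels(ft)
  spec <- stackingSpec(base = list(learnerSpec("knn"),
                                   learnerSpec("dt", list(max_depth = 5L)),
                                   learnerSpec("dt", list(max_depth = 2L))),
                       meta = learnerSpec("dt", list(max_depth = 5L)),
                       passthrough = FALSE)
  m <- fitStacking(X, y, spec)
  expect_identical(predictStacking(m, X)$label,
                   eegstack:::.asBinaryLabel(y))
})

test_that("subject-grouped CV does not trail epoch-level CV by a large leakage gap", {
  gaps <- vapply(1:3, function(r) {
    cohort <- generateCohort(tinyCohortSpec(nMdd = 5, nHc = 5, seed = 1200 + r,
                                            effect = strongGlobalEffect()))
    ft <- tinyFeatures(cohort)
    accS <- reportMetrics(crossValidate(ft, k = 5, grouping = "subject",
                                        seed = r))$accuracy
    accE <- reportMetrics(crossValidate(ft, k = 5, grouping = "epoch",
                                        seed = r))$accuracy
    accE - accS
  }, numeric(1))
  expect_lte(mean(gaps), 0.15)
})
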