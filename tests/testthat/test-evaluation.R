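test_that("confusion metrics reproduce the worked example and edge cases", {
  m <- confusionMetrics(tp = 8, fp = 1, tn = 9, fn = 2)
  expect_equal(unname(m["accuracy"]), 0.85, tolerance = 1e-9)
  expect_equal(unname(m["recall"]), 0.8, tolerance = 1e-9)
  expect_equal(unname(m["f1"]), 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8),
               tolerance = 1e-9)
  perfect <- confusionMetrics(10, 0, 0, 0)
  expect_identical(unname(perfect[c("accuracy", "recall", "f1")]), c(1, 1, 1))
  inverted <- confusionMetrics(0, 10, 0, 10)
  expect_identical(unname(inverted[c("accuracy", "recall", "f1")]), c(0, 0, 0))
  expect_error(confusionMetrics(-1, 0, 0, 1), "non-negative")
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("confusion metrics match direct arithmetic on random counts", {
  for (s in 1:200) {
    cnt <- withr::with_seed(s, sample(0:30, 4, replace = TRUE))
    if (sum(cnt) == 0) next
    m <- confusionMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(unname(m["accuracy"]), (cnt[1] + cnt[3]) / sum(cnt),
                 tolerance = 1e-12)
    if (cnt[1] + cnt[4] > 0)
      expect_equal(unname(m["recall"]), cnt[1] / (cnt[1] + cnt[4]),
                   tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_identical(rocAuc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_identical(rocAuc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  hand <- c(0.9, 0.8, 0.8, 0.4, 0.7, 0.6, 0.3, 0.8)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_identical(rocAuc(hand, lab), aucOracle(hand, lab))
  for (s in 1:500) {
    n <- withr::with_seed(s, sample(4:20, 1))
    scores <- withr::with_seed(s + 5000,
                               round(runif(2 * n), 2))   # force some ties
    labels <- rep(c(1, 0), n)
    expect_identical(rocAuc(scores, labels), aucOracle(scores, labels))
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  # cross-check against an established ROC implementation
  sc <- withr::with_seed(77, runif(60))
  lb <- rep(c(1, 0), 30)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(rocAuc(sc, lb), ref, tolerance = 1e-12)
})

test_that("quartile convention is linear interpolation (type 7)", {
  vals <- matrix(rep(c(1, 2, 3, 4, 5), 2), ncol = 2)
  colnames(vals) <- c("Frontal__alpha_power", "Frontal__total_power")
  vals[, 2] <- 10
  ft <- FeatureTable(vals, labels = rep(c("MDD", "HC"), c(3, 2)),
                     subjectIds = paste0("s", 1:5))
  rep <- bandPowerGroupReport(ft, regions = "Frontal", bands = "alpha")
  pooled <- quantile(c(1, 2, 3, 4, 5) / 10, c(0.25, 0.5, 0.75), type = 7)
  mdd <- rep$summary[rep$summary$group == "MDD", ]
  expect_equal(mdd$median, median(c(1, 2, 3) / 10), tolerance = 1e-12)
  expect_equal(mdd$q1, unname(quantile(c(1, 2, 3) / 10, 0.25)), tolerance = 1e-12)
  expect_equal(mdd$q3, unname(quantile(c(1, 2, 3) / 10, 0.75)), tolerance = 1e-12)
  expect_true(all(c("median", "q1", "q3", "n_outliers") %in% names(rep$summary)))
})

test_that("band-power report flags no differences between identical groups", {
  X <- withr::with_seed(2, matrix(abs(rnorm(40 * 4)) + 1, 40, 4))
  colnames(X) <- c("Frontal__alpha_power", "Frontal__theta_power",
                   "Frontal__total_power", "Frontal__gamma_power")
  half <- X[1:20, ]
  ft <- FeatureTable(rbind(half, half),
                     labels = rep(c("MDD", "HC"), each = 20),
                     subjectIds = paste0("s", 1:40))
  rep <- bandPowerGroupReport(ft, regions = "Frontal",
                              bands = c("alpha", "theta", "gamma"))
  expect_true(all(rep$tests$p_value >= 0.99))
  p <- plotBandPowers(rep)
  expect_s3_class(p, "ggplot")
})

test_that("a theta effect shifts the MDD median relative theta upward in-scope", {
  cohort <- generateCohort(cohortSpec(nMdd = 4, nHc = 4, durationSeconds = 16,
                                      seed = 41,
                                      effect = effectMap(delta = 1, theta = 1.5,
                                                         alpha = 1, beta1 = 1,
                                                         beta2 = 1, gamma = 1,
                                                         blinkRate = 0,
                                                         lineNoiseAmplitude = 0)))
  ft <- tinyFeatures(cohort)
  rep <- bandPowerGroupReport(ft, bands = "theta")
  med <- rep$summary
  for (r in unique(med$region)) {
    mdd <- med$median[med$region == r & med$group == "MDD"]
    hc <- med$median[med$region == r & med$group == "HC"]
    expect_gt(mdd, hc)
  }
})

test_that("region ablation reports one ranked row per region", {
  cohort <- generateCohort(tinyCohortSpec(nMdd = 4, nHc = 4, seed = 23,
                                          effect = strongGlobalEffect()))
  ft <- tinyFeatures(cohort)
  rep <- regionAblation(ft, k = 4, seed = 2)
  m <- reportMetrics(rep)
  expect_identical(nrow(m), 5L)
  expect_setequal(m$region, names(defaultRegionMap()))
  expect_true(all(diff(m$accuracy) <= 0))          # ranked by accuracy
  expect_true(all(m$n_selected <= 19L))
})
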