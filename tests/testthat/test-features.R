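fs <- 256

test_that("Welch PSD concentrates a tone, conserves white-noise power, and averages segments", {
  t <- seq(1 / fs, 32, 1 / fs)
  psd <- welchPsd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd$freqs[which.max(psd$power)], 10, tolerance = 0.26)
  # Parseval consistency: integrated PSD ~ variance, averaged over seeds
  ratios <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(fs * 16, sd = 2))
    simpsonIntegral(welchPsd(x, fs)$power, welchPsd(x, fs)$freqs) / var(x)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
  # K identical segments equal one periodogram
  seg <- withr::with_seed(1, rnorm(fs * 4))
  one <- welchPsd(seg, fs, segmentSeconds = 4)
  rep3 <- welchPsd(rep(seg, 3), fs, segmentSeconds = 4, overlapFraction = 0)
  expect_equal(rep3$power, one$power, tolerance = 1e-10)
  expect_error(welchPsd(rnorm(100), fs), "shorter")
})

test_that("band powers integrate correctly and relative powers stay bounded", {
  t <- seq(1 / fs, 32, 1 / fs)
  psd <- welchPsd(sin(2 * pi * 10 * t), fs)
  bp <- bandPowers(psd)
  expect_gte(bp$relative[["alpha"]], 0.95)
  expect_lte(sum(bp$relative), 1 + 1e-9)
  # equal-amplitude 6 Hz + 25 Hz lines split power between theta and beta2
  psd2 <- welchPsd(sin(2 * pi * 6 * t) + sin(2 * pi * 25 * t), fs)
  bp2 <- bandPowers(psd2)
  expect_equal(bp2$relative[["theta"]], bp2$relative[["beta2"]],
               tolerance = 0.1 * bp2$relative[["theta"]])
  expect_error(bandPowers(psd, list(high = c(100, 140))), "outside")
})

test_that("center frequencies: centroid, argmax and low-frequency tie-break", {
  t <- seq(1 / fs, 32, 1 / fs)
  cf <- centerFrequencies(welchPsd(sin(2 * pi * 10 * t), fs))
  expect_equal(unname(cf["centroid"]), 10, tolerance = 0.5)
  expect_equal(unname(cf["peak"]), 10, tolerance = 0.26)
  cf2 <- centerFrequencies(welchPsd(sin(2 * pi * 8 * t) + sin(2 * pi * 12 * t), fs))
  expect_equal(unname(cf2["centroid"]), 10, tolerance = 0.5)
  # exact tie -> lower frequency wins
  fake <- structure(list(freqs = c(0, 1, 2, 3, 4), power = c(0, 0, 5, 0, 5),
                         fs = 10, M = 8, R = 4, K = 1, window = "hann"),
                    class = "PSDEstimate")
  expect_identical(unname(centerFrequencies(fake)["peak"]), 2)
})

test_that("temporal statistics match moment definitions", {
  expect_identical(unname(temporalStats(c(1, 2, 3, 4))["peak"]), 4)
  x <- withr::with_seed(9, rnorm(1e5))
  ts <- temporalStats(x)
  expect_lt(abs(ts["skewness"]), 0.1)
  expect_lt(abs(ts["kurtosis"]), 0.2)
  const <- temporalStats(rep(3, 10))
  expect_identical(as.numeric(const), c(0, 0, 3))
  expect_true(attr(const, "degenerate"))
})

test_that("sample entropy: analytic limits and ordering", {
  expect_identical(sampleEntropy(rep(1, 100), m = 2, r = 0.2), 0)
  ok <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(2048))
    sine <- sin(2 * pi * 10 * seq_len(2048) / fs)
    sine <- sine / sd(sine) * sd(x)
    sampleEntropy(x, 2, 0.2 * sd(x)) > sampleEntropy(sine, 2, 0.2 * sd(sine))
  }, logical(1))
  expect_true(all(ok))
  expect_error(sampleEntropy(1:3, m = 2), "too short")
})

test_that("sample entropy equals the brute-force oracle on random short series", {
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(20:100, 1))
    x <- withr::with_seed(s + 1000, rnorm(n))
    r <- 0.25 * sd(x)
    counts <- sampenOracle(x, 2, r)
    expected <- if (counts["B"] == 0) Inf else
      if (counts["A"] == 0) log(counts[["B"]]) + log(n - 2) else
        -log(counts[["A"]] / counts[["B"]])
    expect_identical(as.numeric(sampleEntropy(x, 2, r)), as.numeric(expected))
  }
})

test_that("Higuchi dimension: line, noise, and oracle curve lengths", {
  expect_equal(as.numeric(higuchiFD(seq_len(1000))), 1, tolerance = 0.05)
  d <- vapply(1:20, function(s)
    as.numeric(higuchiFD(withr::with_seed(s, rnorm(4096)), 10)), numeric(1))
  expect_equal(mean(d), 2, tolerance = 0.1)
  for (s in 1:100) {
    x <- withr::with_seed(s, rnorm(100))
    expect_equal(eegstack:::.higuchiLengths(x, 8L), higuchiOracle(x, 8),
                 tolerance = 1e-10)
  }
  expect_true(attr(higuchiFD(rep(2, 100)), "degenerate"))
})

test_that("Hurst exponent separates noise from random walks and is reversal-invariant", {
  h <- vapply(1:20, function(s)
    hurstExponent(withr::with_seed(s, rnorm(8192))), numeric(1))
  expect_gte(mean(h), 0.4); expect_lte(mean(h), 0.6)
  hw <- vapply(1:20, function(s)
    hurstExponent(withr::with_seed(s, cumsum(rnorm(8192)))), numeric(1))
  expect_gte(mean(hw), 0.85)
  x <- withr::with_seed(31, rnorm(500))
  expect_identical(hurstExponent(x), hurstExponent(rev(x)))
  expect_true(attr(hurstExponent(rep(1, 100)), "degenerate"))
})

test_that("Shannon entropy: constant, two-level and uniform-fill limits", {
  expect_identical(as.numeric(shannonEntropy(rep(5, 200))), 0)
  square <- rep(c(-1, 1), 100)
  for (nb in c(2L, 8L, 128L))
    expect_equal(shannonEntropy(square, nb), log(2), tolerance = 1e-12)
  # exactly equal occupancy of all bins
  uniform <- rep(seq(0, 1, length.out = 16), each = 5)
  expect_equal(shannonEntropy(uniform, 16L), log(16), tolerance = 1e-12)
})

test_that("C0 complexity: literal FFT amplitude and standard irregularity", {
  x <- sin(2 * pi * 8 * seq_len(1024) / fs)     # grid frequency
  expect_equal(c0Complexity(x, "paper_literal"), 1, tolerance = 1e-6)
  expect_lte(c0Complexity(x, "standard"), 0.01)
  expect_identical(c0Complexity(rep(0, 64), "paper_literal"), 0)
  expect_identical(c0Complexity(rep(0, 64), "standard"), 0)
})

test_that("time-frequency energies: zero, quadratic scaling, stationarity", {
  expect_identical(unname(tfEnergy(rep(0, 1024), fs)), c(0, 0))
  x <- withr::with_seed(5, rnorm(1024))
  e1 <- tfEnergy(x, fs); e3 <- tfEnergy(3 * x, fs)
  expect_equal(unname(e3), unname(9 * e1), tolerance = 1e-9)
  expect_error(tfEnergy(rnorm(100), fs), "longer")
})

test_that("feature table has the full region-wise schema and provenance", {
  cohort <- generateCohort(tinyCohortSpec(nMdd = 2, nHc = 2, seed = 17))
  ft <- tinyFeatures(cohort)
  expect_identical(nrow(ft), 95L)       # features are SE rows
  cats <- table(featureSchema()[sub("^.*__", "", rownames(ft))])
  expect_identical(as.integer(cats[c("spectral", "temporal", "nonlinear",
                                     "timefrequency")]),
                   c(45L, 15L, 25L, 10L))
  expect_identical(ncol(ft), 16L)       # 4 subjects x 4 retained epochs
  expect_setequal(unique(epochLabels(ft)), c("MDD", "HC"))
  # a region of identical channels reproduces the single-channel features
  sig <- withr::with_seed(3, rnorm(1024))
  eps <- epochRecording(EEGRecording(
    matrix(rep(sig, 19), nrow = 19, byrow = TRUE,
           dimnames = list(eegstack:::.STANDARD_1020, NULL)), fs,
    subjectId = "T", group = "HC"), 4, 0)
  ft2 <- buildFeatureTable(list(eps))
  single <- channelFeatures(sig, fs)
  expect_equal(unname(featureMatrix(ft2)[1, paste0("Central__",
                                                   names(single))]),
               unname(single), tolerance = 1e-12)
})

test_that("feature extraction is deterministic and scale-covariant", {
  x <- withr::with_seed(8, rnorm(1024, sd = 5))
  f1 <- channelFeatures(x, fs)
  expect_identical(f1, channelFeatures(x, fs))
  c_ <- 3.7
  f2 <- channelFeatures(c_ * x, fs)
  invariant <- c("skewness", "kurtosis", "sample_entropy", "higuchi_fd",
                 "hurst", "shannon_entropy")
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-8)
  expect_equal(f2[["peak"]], c_ * f1[["peak"]], tolerance = 1e-9)
  quads <- c("delta_power", "theta_power", "alpha_power", "beta1_power",
             "beta2_power", "gamma_power", "total_power",
             "mean_tf_energy", "max_tf_energy")
  expect_equal(unname(f2[quads]), unname(c_^2 * f1[quads]), tolerance = 1e-9)
  # relative band powers are scale-free
  r1 <- bandPowers(welchPsd(x, fs))$relative
  r2 <- bandPowers(welchPsd(c_ * x, fs))$relative
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("stationary tones have uniform per-window spectrogram maxima", {
  x <- sin(2 * pi * 10 * seq_len(8 * fs) / fs)
  perWindow <- vapply(0:7, function(w)
    tfEnergy(x[(w * fs + 1):((w + 1) * fs)], fs)["max_energy"], numeric(1))
  expect_lt(diff(range(perWindow)) / mean(perWindow), 0.1)
})
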