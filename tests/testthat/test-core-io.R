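test_that("array-bundle round trip is lossless", {
  set.seed(4)
  rec <- EEGRecording(matrix(rnorm(5 * 128), 5, 128,
                             dimnames = list(c("Fp1", "Fp2", "F3", "F4", "Cz"), NULL)),
                      fs = 256, subjectId = "S9", group = "MDD",
                      annotations = list(note = "x"))
  pfx <- file.path(withr::local_tempdir(), "rec")
  writeRecording(rec, pfx)
  back <- readRecording(pfx)
  expect_identical(signalData(back), signalData(rec))
  expect_identical(channelNames(back), channelNames(rec))
  expect_identical(samplingRate(back), 256)
  expect_identical(subjectId(back), "S9")
  expect_identical(groupLabel(back), "MDD")
})

test_that("EDF round trip preserves shape and stays within quantization error", {
  spec <- tinyCohortSpec(nMdd = 1, nHc = 1, durationSeconds = 4, seed = 8)
  rec <- generateRecording("E1", "HC", spec, 21)
  path <- file.path(withr::local_tempdir(), "a.edf")
  writeEDF(rec, path, physicalMax = 200)
  back <- readEDF(path)
  expect_identical(channelNames(back), channelNames(rec))
  expect_identical(samplingRate(back), 256)
  expect_lt(max(abs(signalData(back) - signalData(rec))), 0.1)
  # zero signal round-trips to zero
  z <- EEGRecording(matrix(0, 2, 512, dimnames = list(c("A", "B"), NULL)), 256)
  pz <- file.path(withr::local_tempdir(), "z.edf")
  writeEDF(z, pz)
  expect_true(all(abs(signalData(readEDF(pz))) < 1e-6))
  # out-of-range amplitudes are rejected
  expect_error(writeEDF(rec, path, physicalMax = 1), "physical range")
})

test_that("EDF physical units in millivolts are rescaled to microvolts", {
  rec <- EEGRecording(matrix(sin(seq_len(512) / 10) * 0.05, 1, 512,
                             dimnames = list("Fp1", NULL)), 256)
  path <- file.path(withr::local_tempdir(), "mv.edf")
  writeEDF(rec, path, physicalMax = 1)
  # rewrite the dimension field (offset 256 + 16 + 80 within the header)
  con <- file(path, "r+b")
  seek(con, 256 + 16 + 80, rw = "write")
  writeChar(formatC("mV", width = 8, flag = "-"), con, eos = NULL)
  close(con)
  back <- readEDF(path)
  expect_equal(signalData(back)[1, ], signalData(rec)[1, ] * 1000,
               tolerance = 1e-3)
})

test_that("channel standardization drops bookkeeping channels and cleans names", {
  nm <- c("EEG Fp1-LE", "EEG F7-LE", "EEG T3-LE", "EEG A2-A1",
          "EEG 23A-23R", "EEG 24A-24R")
  rec <- EEGRecording(matrix(seq_len(6 * 4), 6, 4, dimnames = list(nm, NULL)), 256)
  std <- standardizeChannels(rec)
  expect_identical(channelNames(std), c("Fp1", "F7", "T3"))
  expect_identical(unname(signalData(std)), unname(signalData(rec)[1:3, ]))
  # empty drop list + explicit rename leaves data untouched
  one <- EEGRecording(matrix(1:8, 1, 8, dimnames = list("EEG T3-LE", NULL)), 128)
  ren <- standardizeChannels(one, drop = character(), rename = c("EEG T3-LE" = "T3"))
  expect_identical(channelNames(ren), "T3")
  expect_identical(unname(signalData(ren)), unname(signalData(one)))
  expect_error(standardizeChannels(rec, drop = nm), "all channels dropped")
})

test_that("default region map matches the montage partition", {
  map <- defaultRegionMap()
  expect_length(map, 5L)
  expect_identical(regionChannels(map, "Left Temporal"), c("F7", "T3", "T5"))
  expect_identical(regionChannels(map, "Central"), c("C3", "C4", "Fz", "Cz", "Pz"))
  expect_identical(lengths(map, use.names = FALSE), c(4L, 3L, 4L, 3L, 5L))
  all_ch <- unlist(map, use.names = FALSE)
  expect_length(all_ch, 19L)
  expect_false(anyDuplicated(all_ch) > 0)
  expect_error(regionChannels(map, "Occipital"), "Left Temporal")
})

test_that("band schemes are validated and ordered", {
  b <- bandScheme("standard")
  expect_identical(names(b), c("delta", "theta", "alpha", "beta1", "beta2", "gamma"))
  expect_identical(b$alpha, c(8, 13))
  expect_identical(bandScheme("table2")$alpha, c(8, 11))
  expect_error(eegstack:::.validateBandScheme(list(a = c(1, 5), b = c(4, 8))),
               "overlap")
})

test_that("feature table and selection/eval artifacts round-trip through CSV/JSON", {
  ft <- gaussianTable(n = 12, p = 4, seed = 7)
  fp <- file.path(withr::local_tempdir(), "ft.csv")
  writeFeatureTable(ft, fp)
  back <- readFeatureTable(fp)
  expect_equal(featureMatrix(back), featureMatrix(ft), tolerance = 1e-12)
  expect_identical(epochLabels(back), epochLabels(ft))

  sel <- selectFeatures(ft, alpha = 0.5)$result
  sp <- file.path(withr::local_tempdir(), "sel.csv")
  writeSelectionResult(sel, sp)
  sback <- readSelectionResult(sp)
  expect_equal(selectionStats(sback)$raw_p, selectionStats(sel)$raw_p,
               tolerance = 1e-12)

  rep <- crossValidate(ft, list(dt = learnerSpec("dt")), k = 2,
                       grouping = "epoch", seed = 1)
  rp <- file.path(withr::local_tempdir(), "rep.json")
  writeEvalReport(rep, rp)
  rback <- readEvalReport(rp)
  expect_equal(reportMetrics(rback)$accuracy, reportMetrics(rep)$accuracy,
               tolerance = 1e-12)
})
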