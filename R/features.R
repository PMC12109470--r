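#' @include AllClasses.R psd.R nonlinear.R temporal.R
NULL

.FEATURE_SCHEMA <- c(
  center_freq_relative = "spectral", center_freq_absolute = "spectral",
  delta_power = "spectral", theta_power = "spectral", alpha_power = "spectral",
  beta1_power = "spectral", beta2_power = "spectral", gamma_power = "spectral",
  total_power = "spectral",
  skewness = "temporal", kurtosis = "temporal", peak = "temporal",
  sample_entropy = "nonlinear", higuchi_fd = "nonlinear",
  hurst = "nonlinear", shannon_entropy = "nonlinear",
  c0_complexity = "nonlinear",
  mean_tf_energy = "timefrequency", max_tf_energy = "timefrequency"
)

#' Feature schema
#'
#' The 19 per-region features: 9 spectral, 3 temporal, 5 nonlinear and 2
#' time-frequency. With the default 5-region map this yields the
#' 95-column table (45 + 15 + 25 + 10).
#'
#' @return named character vector mapping feature name to category.
#' @export
featureSchema <- function() .FEATURE_SCHEMA

#' Feature-extraction parameters
#'
#' @param welchSegmentSeconds,welchOverlap Welch PSD segment length (s) and
#'   fractional overlap; one full-range PSD is shared by all spectral
#'   features so relative powers stay consistent.
#' @param sampenM,sampenR sample-entropy embedding length and tolerance
#'   factor (`r = sampenR * sd(epoch)`).
#' @param higuchiKmax Higuchi maximum scale factor.
#' @param shannonBins amplitude-histogram bins for Shannon entropy.
#' @param stftWindowSeconds,stftOverlap STFT window (s) and overlap for the
#'   time-frequency energies.
#' @param c0Mode C0 complexity mode (see [c0Complexity()]).
#' @return list of parameters for [buildFeatureTable()].
#' @export
featureParams <- function(welchSegmentSeconds = 4, welchOverlap = 0.5,
                          sampenM = 2L, sampenR = 0.2, higuchiKmax = 10L,
                          shannonBins = 128L, stftWindowSeconds = 1,
                          stftOverlap = 0.5,
                          c0Mode = c("paper_literal", "standard")) {
  list(welchSegmentSeconds = welchSegmentSeconds, welchOverlap = welchOverlap,
       sampenM = sampenM, sampenR = sampenR, higuchiKmax = higuchiKmax,
       shannonBins = shannonBins, stftWindowSeconds = stftWindowSeconds,
       stftOverlap = stftOverlap, c0Mode = match.arg(c0Mode))
}

#' Full feature vector of a single-channel epoch
#'
#' @param x numeric epoch signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param bands a [bandScheme()].
#' @param params a [featureParams()] list.
#' @return named numeric of length 19 (see [featureSchema()]).
#' @export
channelFeatures <- function(x, fs, bands = bandScheme("standard"),
                            params = featureParams()) {
  psd <- welchPsd(x, fs, params$welchSegmentSeconds, params$welchOverlap)
  bp <- bandPowers(psd, bands)
  cf <- if (all(psd$power == 0)) c(centroid = 0, peak = 0) else centerFrequencies(psd)
  ts <- temporalStats(x)
  se <- if (sd(x) == 0) 0 else
    as.numeric(sampleEntropy(x, params$sampenM, params$sampenR * sd(x)))
  if (!is.finite(se)) se <- log(length(x))        # B = 0 sentinel, capped
  out <- c(
    center_freq_relative = unname(cf["centroid"]),
    center_freq_absolute = unname(cf["peak"]),
    setNames(unname(bp$absolute), paste0(names(bands), "_power")),
    total_power = bp$total,
    skewness = unname(ts["skewness"]), kurtosis = unname(ts["kurtosis"]),
    peak = unname(ts["peak"]),
    sample_entropy = se,
    higuchi_fd = as.numeric(higuchiFD(x, params$higuchiKmax)),
    hurst = as.numeric(hurstExponent(x)),
    shannon_entropy = as.numeric(shannonEntropy(x, params$shannonBins)),
    c0_complexity = c0Complexity(x, params$c0Mode),
    setNames(tfEnergy(x, fs, params$stftWindowSeconds, params$stftOverlap),
             c("mean_tf_energy", "max_tf_energy"))
  )
  out[names(.FEATURE_SCHEMA)]
}

#' Build the region-wise feature table
#'
#' For every retained epoch of every subject, the 19 features are computed
#' per channel and then averaged over each region's channels (arithmetic
#' mean), producing one row per epoch with columns named
#' `"<region>__<feature>"` — 95 columns under the default 5-region map.
#'
#' @param epochSets list of [EpochSet-class] objects sharing sampling rate
#'   and channel names.
#' @param regions a region map, e.g. [defaultRegionMap()].
#' @param bands a [bandScheme()].
#' @param params a [featureParams()] list.
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(epochSets, regions = defaultRegionMap(),
                              bands = bandScheme("standard"),
                              params = featureParams()) {
  stopifnot(length(epochSets) >= 1L)
  .validateRegionMap(regions)
  fs <- samplingRate(epochSets[[1L]])
  chans <- channelNames(epochSets[[1L]])
  for (es in epochSets) {
    stopifnot(is(es, "EpochSet"))
    if (samplingRate(es) != fs || !identical(channelNames(es), chans))
      stop("all epoch sets must share sampling rate and channel names")
  }
  needed <- unlist(regions, use.names = FALSE)
  missing <- setdiff(needed, chans)
  if (length(missing))
    stop("region channels missing from recordings: ",
         paste(missing, collapse = ", "))
  featNames <- names(.FEATURE_SCHEMA)
  colNames <- unlist(lapply(names(regions), function(r)
    paste0(r, "__", featNames)), use.names = FALSE)

  rows <- list(); labs <- character(); subs <- character()
  for (es in epochSets) {
    keep <- which(retainedMask(es))
    for (e in keep) {
      perChan <- vapply(needed, function(ch)
        channelFeatures(es@epochs[e, ch, ], fs, bands, params),
        numeric(length(featNames)))
      row <- unlist(lapply(regions, function(rchans)
        rowMeans(perChan[, rchans, drop = FALSE])), use.names = FALSE)
      rows[[length(rows) + 1L]] <- row
      labs <- c(labs, groupLabel(es))
      subs <- c(subs, subjectId(es))
    }
  }
  if (!length(rows)) stop("no retained epochs to build a feature table from")
  vals <- do.call(rbind, rows)
  colnames(vals) <- colNames
  if (anyNA(vals)) stop("feature extraction produced NA values")
  FeatureTable(vals, labels = labs, subjectIds = subs)
}
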