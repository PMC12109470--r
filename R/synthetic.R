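#' @include AllClasses.R regions-bands.R
NULL

#' Group-effect map for synthetic cohorts
#'
#' Describes how the MDD group's signal differs from controls and which
#' nuisance components are present. Band factors multiply the MDD group's
#' band *amplitude* (so power scales with the square); `1.0` means no
#' effect. Defaults encode the resting-state picture of depression used
#' throughout: relatively higher theta, alpha and beta power, lower gamma,
#' delta unchanged.
#'
#' @param delta,theta,alpha,beta1,beta2,gamma multiplicative amplitude
#'   factors (> 0) applied to the MDD group.
#' @param regionScope optional character vector of region names (per
#'   `regionMap`) restricting where the factors apply; `NULL` = whole scalp.
#' @param blinkRate frontal blink transients per minute (>= 0).
#' @param lineNoiseAmplitude 50 Hz mains sinusoid amplitude, uV.
#' @param backgroundExponent spectral slope of the 1/f^a background.
#' @param backgroundAmplitude RMS of the 1/f background, uV.
#' @param baseBandAmplitudes named numeric, per-band RMS amplitude (uV) of
#'   the band-limited carriers common to both groups.
#' @return a list of class `"EffectMap"`.
#' @export
effectMap <- function(delta = 1, theta = 1.2, alpha = 1.2, beta1 = 1.15,
                      beta2 = 1.15, gamma = 0.85, regionScope = NULL,
                      blinkRate = 12, lineNoiseAmplitude = 5,
                      backgroundExponent = 1, backgroundAmplitude = 6,
                      baseBandAmplitudes = c(delta = 8, theta = 5, alpha = 10,
                                             beta1 = 4, beta2 = 3, gamma = 2)) {
  factors <- c(delta = delta, theta = theta, alpha = alpha,
               beta1 = beta1, beta2 = beta2, gamma = gamma)
  if (any(factors <= 0)) stop("band effect factors must be positive")
  if (blinkRate < 0) stop("blinkRate must be non-negative")
  structure(list(factors = factors, regionScope = regionScope,
                 blinkRate = blinkRate,
                 lineNoiseAmplitude = lineNoiseAmplitude,
                 backgroundExponent = backgroundExponent,
                 backgroundAmplitude = backgroundAmplitude,
                 baseBandAmplitudes = baseBandAmplitudes),
            class = "EffectMap")
}

#' Null effect map (identical groups)
#' @inheritParams effectMap
#' @export
nullEffectMap <- function(blinkRate = 0, lineNoiseAmplitude = 0)
  effectMap(delta = 1, theta = 1, alpha = 1, beta1 = 1, beta2 = 1, gamma = 1,
            blinkRate = blinkRate, lineNoiseAmplitude = lineNoiseAmplitude)

#' Cohort specification
#'
#' @param nMdd,nHc subject counts per group (defaults mirror the reference
#'   cohort of 34 patients and 30 controls).
#' @param durationSeconds recording length in seconds (default 160 s, long
#'   enough for the standard 30-155 s crop).
#' @param fs sampling rate, Hz.
#' @param effect an [effectMap()].
#' @param bands band scheme used to place the oscillatory carriers.
#' @param regionMap scalp regions used to resolve `regionScope`.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return a list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(nMdd = 34, nHc = 30, durationSeconds = 160, fs = 256,
                       effect = effectMap(), bands = bandScheme("standard"),
                       regionMap = defaultRegionMap(), seed = 1) {
  stopifnot(nMdd >= 0, nHc >= 0, nMdd + nHc >= 2, durationSeconds > 0, fs > 0)
  structure(list(nMdd = as.integer(nMdd), nHc = as.integer(nHc),
                 durationSeconds = durationSeconds, fs = fs, effect = effect,
                 bands = bands, regionMap = regionMap,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Band-limited Gaussian noise via FFT masking with raised-cosine edges
# (rollOff Hz wide), normalized to unit RMS.
.bandNoise <- function(n, fs, lo, hi, rollOff = 0.5) {
  x <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                        # two-sided frequency axis
  mask <- rep(0, n)
  mask[f >= lo & f <= hi] <- 1
  edge <- f >= lo - rollOff & f < lo
  mask[edge] <- 0.5 * (1 + cos(pi * (lo - f[edge]) / rollOff))
  edge <- f > hi & f <= hi + rollOff
  mask[edge] <- 0.5 * (1 + cos(pi * (f[edge] - hi) / rollOff))
  y <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) rep(0, n) else y / s
}

# 1/f^a background noise, unit RMS. Spectrum shaped below by a 0.3 Hz knee
# so the amplitude stays finite at the lowest resolvable frequencies.
.pinkNoise <- function(n, fs, exponent) {
  x <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 0.3, 0, pmax(f, 0.3)^(-exponent / 2))
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) rep(0, n) else y / s
}

#' Generate one synthetic resting-EEG recording
#'
#' Each channel is a sum of band-limited noise carriers (one per frequency
#' band, filtered white noise so that spectra are band-shaped and nonlinear
#' features are non-degenerate), a 1/f background, frontal blink
#' transients (hann-shaped pulses, largest on Fp1/Fp2 with scalp falloff)
#' and a common-phase 50 Hz mains sinusoid. For MDD subjects the band
#' amplitudes are multiplied by the effect factors, on all channels or only
#' within `regionScope`. Deterministic given `seed`.
#'
#' @param subjectId subject identifier.
#' @param group `"MDD"` or `"HC"`.
#' @param spec a [cohortSpec()].
#' @param seed integer seed for this subject.
#' @return an [EEGRecording-class] with blink onsets/durations recorded in
#'   `annotations`.
#' @export
generateRecording <- function(subjectId, group, spec, seed) {
  stopifnot(inherits(spec, "CohortSpec"), group %in% c("MDD", "HC"))
  fs <- spec$fs
  n <- round(spec$durationSeconds * fs)
  eff <- spec$effect
  chans <- .STANDARD_1020
  scopeChans <- if (is.null(eff$regionScope)) chans else
    unlist(spec$regionMap[eff$regionScope], use.names = FALSE)

  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    tvec <- seq_len(n) / fs
    linePhase <- runif(1, 0, 2 * pi)
    nBlinks <- rpois(1, eff$blinkRate * spec$durationSeconds / 60)
    blinkOn  <- sort(runif(nBlinks, 0, spec$durationSeconds - 2))
    blinkDur <- runif(nBlinks, 0.3, 2)
    blinkAmp <- runif(nBlinks, 80, 150)
    blinkTrace <- rep(0, n)
    for (b in seq_len(nBlinks)) {
      idx <- round(blinkOn[b] * fs):min(n - 1L, round((blinkOn[b] + blinkDur[b]) * fs))
      tau <- (idx - idx[1L]) / max(1L, length(idx) - 1L)
      blinkTrace[idx + 1L] <- blinkTrace[idx + 1L] +
        blinkAmp[b] * 0.5 * (1 - cos(2 * pi * tau))
    }
    data <- matrix(0, nrow = length(chans), ncol = n,
                   dimnames = list(chans, NULL))
    for (ch in chans) {
      sig <- eff$backgroundAmplitude * .pinkNoise(n, fs, eff$backgroundExponent)
      for (b in names(spec$bands)) {
        amp <- eff$baseBandAmplitudes[[b]]
        if (group == "MDD" && ch %in% scopeChans) amp <- amp * eff$factors[[b]]
        sig <- sig + amp * .bandNoise(n, fs, spec$bands[[b]][1L], spec$bands[[b]][2L])
      }
      blinkW <- switch(ch, Fp1 = 1, Fp2 = 1, F3 = 0.3, F4 = 0.3, 0.05)
      data[ch, ] <- sig + blinkW * blinkTrace +
        eff$lineNoiseAmplitude * sin(2 * pi * 50 * tvec + linePhase)
    }
    EEGRecording(data, fs = fs, subjectId = subjectId, group = group,
                 annotations = list(seed = as.integer(seed %% .Machine$integer.max),
                                    blink_onsets = blinkOn,
                                    blink_durations = blinkDur))
  })
}

# Per-subject seed derived deterministically from the master seed; kept
# below 2^31.
.subjectSeed <- function(masterSeed, index)
  as.integer((as.double(masterSeed) * 1000003 + index * 7919) %% 2147483647)

#' Generate a full two-group cohort
#'
#' @param spec a [cohortSpec()].
#' @return list of [EEGRecording-class] objects (MDD subjects first), with
#'   subject ids `"MDD01"..., "HC01"...`.
#' @examples
#' cohort <- generateCohort(cohortSpec(nMdd = 1, nHc = 1, durationSeconds = 10,
#'                                     effect = nullEffectMap()))
#' vapply(cohort, groupLabel, "")
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  ids <- c(sprintf("MDD%02d", seq_len(spec$nMdd)),
           sprintf("HC%02d", seq_len(spec$nHc)))
  groups <- rep(c("MDD", "HC"), c(spec$nMdd, spec$nHc))
  lapply(seq_along(ids), function(i)
    generateRecording(ids[i], groups[i], spec, .subjectSeed(spec$seed, i)))
}
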