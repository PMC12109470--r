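#' @include AllClasses.R
NULL

#' Temporal distribution statistics
#'
#' Skewness is the standardized third central moment, kurtosis the
#' standardized fourth central moment minus 3 (Fisher convention: a normal
#' distribution gives 0), and peak the maximum absolute amplitude. A
#' zero-variance series reports skewness and kurtosis of 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x numeric series, length >= 2.
#' @return named numeric: `skewness`, `kurtosis`, `peak`.
#' @export
temporalStats <- function(x) {
  stopifnot(length(x) >= 2L)
  peak <- max(abs(x))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    return(structure(c(skewness = 0, kurtosis = 0, peak = peak),
                     degenerate = TRUE))
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3,
    peak = peak)
}

#' Time-frequency energy summary
#'
#' Computes a magnitude-squared short-time Fourier spectrogram (Hann
#' windows) and returns the mean and maximum energy over all
#' time-frequency bins. Both scale with the square of the signal
#' amplitude.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param windowSeconds STFT window length, s (default 1).
#' @param overlapFraction fractional window overlap (default 0.5).
#' @return named numeric: `mean_energy`, `max_energy`.
#' @export
tfEnergy <- function(x, fs, windowSeconds = 1, overlapFraction = 0.5) {
  win <- round(windowSeconds * fs)
  if (win > length(x)) stop("STFT window longer than the signal")
  hop <- max(1L, round(win * (1 - overlapFraction)))
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, win - 1L) / (win - 1L)))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  nf <- win %/% 2L + 1L
  E <- vapply(starts, function(s)
    Mod(fft(w * x[s:(s + win - 1L)])[seq_len(nf)])^2, numeric(nf))
  c(mean_energy = mean(E), max_energy = max(E))
}
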