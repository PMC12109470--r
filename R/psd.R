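#' @include AllClasses.R regions-bands.R
NULL

#' Composite Simpson integration on a uniform grid
#'
#' Simpson's rule over consecutive point triples; when the number of
#' intervals is odd the last interval is handled by the trapezoid rule.
#' Two points fall back to a single trapezoid.
#'
#' @param y sampled integrand.
#' @param x uniformly spaced abscissae (same length as `y`).
#' @return the integral estimate.
#' @export
simpsonIntegral <- function(y, x) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 2L)
  h <- diff(x)
  if (max(h) - min(h) > 1e-8 * max(abs(h)))
    stop("simpsonIntegral expects a uniform grid")
  h <- h[1L]
  nint <- n - 1L
  total <- 0
  if (nint %% 2L == 1L) {           # peel off a trapezoid at the end
    total <- total + h * (y[n - 1L] + y[n]) / 2
    n <- n - 1L
    nint <- nint - 1L
  }
  if (nint >= 2L) {
    i <- seq(1L, n - 2L, by = 2L)
    total <- total + sum(h / 3 * (y[i] + 4 * y[i + 1L] + y[i + 2L]))
  }
  total
}

#' Welch power spectral density estimate
#'
#' Splits the signal into overlapping segments, windows each (Hann taper),
#' averages the one-sided periodograms and normalizes by the window power
#' so that the integrated PSD of white noise matches its variance
#' (units uV^2/Hz).
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param segmentSeconds segment length, s (default 4 s, giving 0.25 Hz
#'   resolution at 256 Hz).
#' @param overlapFraction fractional overlap between segments (default 0.5).
#' @return an object of class `"PSDEstimate"`: list with `freqs` (Hz),
#'   `power` (uV^2/Hz), `fs`, segment length `M`, hop `R`, segment count `K`.
#' @examples
#' psd <- welchPsd(sin(2 * pi * 10 * seq(0, 8, by = 1/256)), fs = 256)
#' psd$freqs[which.max(psd$power)]
#' @export
welchPsd <- function(x, fs, segmentSeconds = 4, overlapFraction = 0.5) {
  M <- round(segmentSeconds * fs)
  if (length(x) < M)
    stop("signal shorter than one Welch segment (", segmentSeconds, " s)")
  R <- max(1L, round(M * (1 - overlapFraction)))
  K <- (length(x) - M) %/% R + 1L
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, M - 1L) / (M - 1L)))   # Hann
  U <- sum(w^2)
  nf <- M %/% 2L + 1L
  acc <- numeric(nf)
  for (m in seq_len(K)) {
    seg <- x[((m - 1L) * R + 1L):((m - 1L) * R + M)]
    X <- fft(w * seg)
    P <- Mod(X[seq_len(nf)])^2 / (fs * U)
    P[2L:(nf - 1L)] <- 2 * P[2L:(nf - 1L)]     # one-sided doubling
    acc <- acc + P
  }
  structure(list(freqs = seq(0L, M %/% 2L) * fs / M, power = acc / K,
                 fs = fs, M = M, R = R, K = K, window = "hann"),
            class = "PSDEstimate")
}

#' @export
print.PSDEstimate <- function(x, ...) {
  cat(sprintf("Welch PSD: %d frequencies 0-%g Hz, %d segments of %d samples (hop %d)\n",
              length(x$freqs), max(x$freqs), x$K, x$M, x$R))
  invisible(x)
}

#' Absolute, total and relative band powers
#'
#' Simpson-integrates the PSD over each band and over the full estimated
#' range; relative power is the ratio of the two.
#'
#' @param psd a `"PSDEstimate"` from [welchPsd()].
#' @param bands a [bandScheme()].
#' @return list with `absolute` (named, uV^2), `total` (uV^2) and
#'   `relative` (named, in \[0, 1\]).
#' @export
bandPowers <- function(psd, bands = bandScheme("standard")) {
  stopifnot(inherits(psd, "PSDEstimate"))
  .validateBandScheme(bands)
  fmax <- max(psd$freqs)
  absolute <- vapply(bands, function(b) {
    if (b[1L] < min(psd$freqs) || b[2L] > fmax)
      stop(sprintf("band %g-%g Hz outside the PSD range (0-%g Hz)",
                   b[1L], b[2L], fmax))
    idx <- which(psd$freqs >= b[1L] & psd$freqs <= b[2L])
    if (length(idx) < 2L)
      stop("PSD grid too coarse for band ", b[1L], "-", b[2L], " Hz")
    simpsonIntegral(psd$power[idx], psd$freqs[idx])
  }, numeric(1L))
  total <- simpsonIntegral(psd$power, psd$freqs)
  list(absolute = absolute, total = total,
       relative = if (total > 0) absolute / total else absolute * 0)
}

#' Spectral centroid and peak frequency
#'
#' The centroid is the Simpson integral of `f * PSD(f)` divided by the
#' integral of `PSD(f)`; the peak is the frequency of the PSD maximum,
#' ties broken toward the lowest frequency.
#'
#' @param psd a `"PSDEstimate"`.
#' @return named numeric: `centroid`, `peak` (Hz).
#' @export
centerFrequencies <- function(psd) {
  stopifnot(inherits(psd, "PSDEstimate"))
  denom <- simpsonIntegral(psd$power, psd$freqs)
  if (denom <= 0) stop("degenerate (all-zero) PSD")
  c(centroid = simpsonIntegral(psd$freqs * psd$power, psd$freqs) / denom,
    peak = psd$freqs[which.max(psd$power)])
}
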