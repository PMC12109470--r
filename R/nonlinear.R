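#' @include AllClasses.R
NULL

# least-squares slope of y on x
.lsSlope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}

#' Sample entropy
#'
#' `SE = -ln(A / B)` where `B` counts pairs of length-`m` embedding vectors
#' within Chebyshev distance `r` of each other and `A` the same pairs
#' extended to length `m + 1`; self-matches are excluded. A constant series
#' gives 0 (`A = B`). `B = 0` returns `Inf`; `A = 0` with `B > 0` returns
#' the saturation cap `ln(B) + ln(N - m)` with attribute
#' `saturated = TRUE`, keeping the feature finite downstream.
#'
#' @param x numeric series, length > m + 1.
#' @param m embedding length (default 2).
#' @param r tolerance; either an absolute value, or the default
#'   `0.2 * sd(x)` when `NULL`.
#' @return the sample entropy (nats).
#' @examples
#' sampleEntropy(rep(1, 100), r = 0.2)   # 0
#' @export
sampleEntropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short: need length > m + 1")
  if (is.null(r)) r <- 0.2 * sd(x)
  if (r <= 0) stop("tolerance r must be positive")
  cnt <- .sampenCounts(as.numeric(x), as.integer(m), as.numeric(r))
  A <- cnt[1L]; B <- cnt[2L]
  if (B == 0) return(Inf)
  if (A == 0)
    return(structure(log(B) + log(n - m), saturated = TRUE))
  -log(A / B)
}

#' Higuchi fractal dimension
#'
#' Average curve lengths `L(k)` are computed at scale factors
#' `k = 1..kmax`; `D` is minus the slope of `log L(k)` against `log k`,
#' clipped to the report range \[1, 2\] (the raw slope is kept in the
#' `raw` attribute). A constant series is degenerate and reports `D = 1`
#' with attribute `degenerate = TRUE`.
#'
#' @param x numeric series, length >= 2 * kmax.
#' @param kmax maximum scale factor (default 10).
#' @return the fractal dimension in \[1, 2\].
#' @export
higuchiFD <- function(x, kmax = 10L) {
  if (length(x) < 2L * kmax) stop("series must be at least 2 * kmax long")
  if (max(x) == min(x))
    return(structure(1, degenerate = TRUE))
  L <- .higuchiLengths(as.numeric(x), as.integer(kmax))
  k <- seq_len(kmax)
  ok <- L > 0
  if (sum(ok) < 2L) return(structure(1, degenerate = TRUE))
  slope <- .lsSlope(log(k[ok]), log(L[ok]))
  structure(min(2, max(1, -slope)), raw = -slope)
}

#' Hurst exponent by rescaled-range analysis
#'
#' For log-spaced window sizes `n`, the series is partitioned into
#' disjoint windows (anchored consistently from both ends so the estimate
#' is invariant under time reversal); in each window the range of the
#' cumulative mean-deviation profile (including its zero origin) is
#' divided by the window standard deviation, and `H` is the slope of
#' `log(R/S)` against `log(n)`. White noise gives about 0.5, a random
#' walk close to 1.
#'
#' @param x numeric series, length >= 64, non-constant.
#' @param minScale smallest window size (default 8).
#' @return the Hurst exponent; a constant series reports 0.5 with
#'   attribute `degenerate = TRUE`.
#' @export
hurstExponent <- function(x, minScale = 8L) {
  n <- length(x)
  if (n < 64L) stop("series must be at least 64 samples long")
  if (max(x) == min(x))
    return(structure(0.5, degenerate = TRUE))
  scales <- 2^(seq.int(floor(log2(minScale)), floor(log2(n / 2))))
  x <- as.numeric(x)
  xr <- rev(x)
  rs <- vapply(scales, function(w) {
    # windows anchored from both ends: time-reversal invariant
    vals <- c(.rsPartition(x, as.integer(w)), .rsPartition(xr, as.integer(w)))
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(structure(0.5, degenerate = TRUE))
  .lsSlope(log(scales[ok]), log(rs[ok]))
}

#' Shannon entropy of the amplitude distribution
#'
#' Amplitudes are binned into `nBins` equal-width bins spanning
#' \[min, max\]; the entropy is `-sum p_i ln p_i` in nats with
#' `0 ln 0 = 0`. A constant series gives 0 (degenerate attribute).
#'
#' @param x numeric series, length >= nBins recommended.
#' @param nBins number of histogram bins (default 128).
#' @return entropy in nats, at most `ln(nBins)`.
#' @export
shannonEntropy <- function(x, nBins = 128L) {
  rng <- range(x)
  if (diff(rng) == 0) return(structure(0, degenerate = TRUE))
  width <- diff(rng) / nBins
  bin <- pmin(floor((x - rng[1L]) / width) + 1L, nBins)
  p <- tabulate(bin, nBins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' C0 complexity
#'
#' Two modes. `"paper_literal"` (default): the maximum single-sided FFT
#' amplitude, `max_k |FFT(x)_k| * 2 / N` over the non-DC bins — a unit
#' sinusoid at a grid frequency gives exactly 1. `"standard"`: the
#' fraction of total spectral power carried by components at or below the
#' mean spectral power (an irregularity ratio in \[0, 1\]; near 0 for a
#' pure tone, near 1 for white noise).
#'
#' @param x numeric series, length >= 8.
#' @param mode `"paper_literal"` or `"standard"`.
#' @return the complexity value; 0 for an all-zero signal in both modes.
#' @export
c0Complexity <- function(x, mode = c("paper_literal", "standard")) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 8L) stop("series must be at least 8 samples long")
  X <- fft(x)
  if (mode == "paper_literal") {
    amp <- Mod(X[2L:(n %/% 2L + 1L)]) * 2 / n
    if (!length(amp)) return(0)
    return(max(amp))
  }
  P <- Mod(X)^2
  tot <- sum(P)
  if (tot == 0) return(0)
  sum(P[P <= mean(P)]) / tot
}
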