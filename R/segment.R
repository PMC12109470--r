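#' @include AllClasses.R
NULL

#' Crop a recording to a time window
#'
#' The default 30-155 s window discards the noisy start and tail of a
#' resting-state recording; the output length is exactly
#' `round((tEnd - tStart) * fs)` samples.
#'
#' @param rec an [EEGRecording-class].
#' @param tStart,tEnd crop window in seconds from recording start.
#' @return the cropped recording.
#' @export
cropRecording <- function(rec, tStart = 30, tEnd = 155) {
  stopifnot(is(rec, "EEGRecording"), tEnd > tStart, tStart >= 0)
  if (duration(rec) < tEnd)
    stop(sprintf("recording is %.1f s long but tEnd = %g s", duration(rec), tEnd))
  idx <- (round(tStart * rec@fs) + 1L):round(tEnd * rec@fs)
  initialize(rec, data = rec@data[, idx, drop = FALSE])
}

#' Cut overlapping fixed-length epochs
#'
#' Epochs start at 0, `window - overlap`, `2 (window - overlap)`, ...;
#' the count is `floor((T - window) / (window - overlap)) + 1`. With the
#' standard 125 s crop, 32 s windows and 1 s overlap this yields exactly
#' 4 epochs. Boundaries are sample-index based.
#'
#' @param rec an [EEGRecording-class].
#' @param window epoch length, s.
#' @param overlap overlap between adjacent epochs, s (`< window`).
#' @return an [EpochSet-class] with all epochs initially retained.
#' @export
epochRecording <- function(rec, window = 32, overlap = 1) {
  stopifnot(is(rec, "EEGRecording"), overlap < window, window > 0)
  fs <- rec@fs
  winS <- round(window * fs)
  strideS <- round((window - overlap) * fs)
  n <- ncol(rec@data)
  if (winS > n)
    stop(sprintf("window (%g s) exceeds recording duration (%.1f s)",
                 window, duration(rec)))
  nEp <- (n - winS) %/% strideS + 1L
  starts <- (seq_len(nEp) - 1L) * strideS
  eps <- array(0, dim = c(nEp, nrow(rec@data), winS),
               dimnames = list(NULL, channelNames(rec), NULL))
  for (e in seq_len(nEp))
    eps[e, , ] <- rec@data[, (starts[e] + 1L):(starts[e] + winS)]
  new("EpochSet", epochs = eps, fs = fs, windowSeconds = window,
      overlapSeconds = overlap, startSeconds = starts / fs,
      retained = rep(TRUE, nEp), subjectId = rec@subjectId,
      group = rec@group)
}

#' Amplitude quality control on epochs
#'
#' An epoch is retained iff every channel's maximum absolute amplitude is
#' at most `reject` (rejects strong artifacts) and every channel's
#' peak-to-peak amplitude is at least `flat` (rejects dead channels). The
#' epoch data are preserved; only the retention mask changes. Idempotent.
#'
#' @param eps an [EpochSet-class].
#' @param reject maximum allowed absolute amplitude, uV.
#' @param flat minimum required peak-to-peak amplitude, uV.
#' @return the epoch set with an updated retention mask.
#' @export
qcEpochs <- function(eps, reject = 100, flat = 1) {
  stopifnot(is(eps, "EpochSet"))
  nEp <- dim(eps@epochs)[1L]
  ok <- vapply(seq_len(nEp), function(e) {
    x <- eps@epochs[e, , , drop = FALSE]
    mx <- apply(abs(x[1L, , , drop = TRUE]), 1L, max)
    ptp <- apply(x[1L, , , drop = TRUE], 1L, function(v) max(v) - min(v))
    all(mx <= reject) && all(ptp >= flat)
  }, logical(1L))
  initialize(eps, retained = eps@retained & ok)
}
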