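#' @include AllClasses.R
NULL

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels, so that at every time
#' point the channel mean is zero. Idempotent; requires at least two
#' channels.
#'
#' @param rec an [EEGRecording-class].
#' @return the re-referenced recording.
#' @export
applyAverageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2L)
    stop("average reference needs at least 2 channels")
  initialize(rec, data = sweep(rec@data, 2L, colMeans(rec@data)))
}

# Linear-phase FIR applied with exact group-delay compensation (the filter
# order is even, so the delay is an integer number of samples). FFT-based
# convolution keeps long filters cheap.
.applyFirZeroPhase <- function(b, x) {
  ord <- length(b) - 1L
  half <- ord %/% 2L
  n <- length(x)
  y <- signal::fftfilt(b, c(x, rep(0, half)))
  y[(half + 1L):(half + n)]
}

# Hamming-window FIR order for a given transition width (Hz); forced even
# so the group delay is integral.
.firOrder <- function(transition, fs) {
  ord <- ceiling(3.3 * fs / transition)
  ord + ord %% 2L
}

#' Band-pass and notch filter a recording
#'
#' A linear-phase Hamming-window FIR band-pass (default 0.5-50 Hz,
#' transition 0.5 Hz at the low edge) applied with group-delay
#' compensation (zero phase), followed by a narrow FIR band-stop around the
#' mains frequency (default 49-51 Hz, attenuating 50 Hz by well over
#' 20 dB). Signal length is preserved.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band-pass edges, Hz.
#' @param notch mains frequency to suppress, Hz; `NA` disables the notch.
#' @param notchHalfWidth half width of the band-stop, Hz.
#' @param transition band-pass transition width at the low edge, Hz.
#' @return the filtered recording.
#' @export
filterRecording <- function(rec, low = 0.5, high = 50, notch = 50,
                            notchHalfWidth = 1, transition = 0.5) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (fs <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  nyq <- fs / 2
  bp <- signal::fir1(.firOrder(transition, fs), c(low, high) / nyq,
                     type = "pass")
  data <- t(apply(rec@data, 1L, function(x) .applyFirZeroPhase(bp, x)))
  if (!is.na(notch)) {
    bs <- signal::fir1(.firOrder(notchHalfWidth, fs),
                       c(notch - notchHalfWidth, notch + notchHalfWidth) / nyq,
                       type = "stop")
    data <- t(apply(data, 1L, function(x) .applyFirZeroPhase(bs, x)))
  }
  dimnames(data) <- dimnames(rec@data)
  initialize(rec, data = data)
}

# Symmetric FastICA (tanh contrast) on a channels x samples matrix.
# Returns the source matrix S (components x samples), the unmixing matrix
# applied to centered data, and the mixing matrix for reconstruction.
.fastICA <- function(X, nComp = nrow(X), seed = 1, maxIter = 200, tol = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  # average-referenced data are rank-deficient by one; whiten on the
  # numerically non-degenerate subspace only
  rank <- sum(eg$values > max(eg$values) * 1e-9)
  nComp <- min(nComp, rank)
  if (nComp < 2L) stop("ICA whitening failed: covariance rank < 2")
  keep <- seq_len(nComp)
  d <- eg$values[keep]
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  W <- withr::with_seed(as.integer(seed), {
    qr.Q(qr(matrix(rnorm(nComp * nComp), nComp)))
  })
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- sym_decor(G %*% t(Z) / n - gp * W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  # Non-convergence of the symmetric rotation is expected when several
  # sources are near-Gaussian (their subspace is rotation-indeterminate);
  # the non-Gaussian artifact components stabilize much earlier, so the
  # flag is reported rather than raised.
  S <- W %*% Z
  unmix <- W %*% K
  mix <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d)) %*% t(W)
  list(S = S, unmixing = unmix, mixing = mix, mean = mu,
       iterations = it, converged = converged)
}

#' Suppress artifact components with ICA
#'
#' Decomposes the recording into independent components (symmetric
#' FastICA, component count = channel count, deterministic given `seed`),
#' zeroes every component whose time course correlates with the frontal
#' proxy (the mean of Fp1 and Fp2 before decomposition) at or above
#' `threshold` in absolute value, and reconstructs the signal.
#'
#' @param rec a filtered [EEGRecording-class] with at least 3 channels,
#'   at least 10 s long, containing Fp1 and Fp2.
#' @param threshold absolute correlation threshold in (0, 1].
#' @param seed ICA initialization seed.
#' @param maxIter,tol FastICA iteration controls.
#' @return list with elements `recording` (cleaned) and `report` (list:
#'   `nComponents`, `removedIndices`, `correlations`, `threshold`, `seed`,
#'   `converged`).
#' @export
removeArtifactComponents <- function(rec, threshold = 0.7, seed = 1,
                                     maxIter = 200, tol = 1e-6) {
  stopifnot(is(rec, "EEGRecording"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (nrow(rec@data) < 3L) stop("ICA needs at least 3 channels")
  if (duration(rec) < 10) stop("ICA needs at least 10 s of signal")
  ch <- channelNames(rec)
  if (!all(c("Fp1", "Fp2") %in% ch))
    stop("frontal proxy requires channels Fp1 and Fp2")
  proxy <- colMeans(rec@data[c("Fp1", "Fp2"), , drop = FALSE])
  dec <- .fastICA(rec@data, seed = seed, maxIter = maxIter, tol = tol)
  cors <- as.vector(cor(t(dec$S), proxy))
  removed <- which(abs(cors) >= threshold)
  S <- dec$S
  if (length(removed)) S[removed, ] <- 0
  data <- dec$mixing %*% S + dec$mean
  dimnames(data) <- dimnames(rec@data)
  report <- list(nComponents = nrow(dec$S), removedIndices = removed,
                 correlations = cors, threshold = threshold,
                 seed = as.integer(seed), converged = dec$converged)
  ann <- rec@annotations
  ann$ica_removed <- removed
  list(recording = initialize(rec, data = data, annotations = ann),
       report = report)
}
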