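#' @include AllClasses.R
NULL

# Minimal EDF (European Data Format) support: ASCII header, one record per
# second, 16-bit little-endian samples. Enough for fixtures and for reading
# plain continuous EDF exports; EDF+ annotations are not interpreted.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range, so the
#' round-trip error is bounded by range / 2^16 (about 0.006 uV for a
#' +/-200 uV signal). The recording must contain a whole number of seconds;
#' the record duration is fixed at 1 s.
#'
#' @param rec an [EEGRecording-class] (microvolts).
#' @param path output file path.
#' @param physicalMax symmetric physical range bound in uV; defaults to the
#'   smallest integer covering the data. Signal amplitudes outside the
#'   declared range are an error.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physicalMax = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (!all(is.finite(rec@data))) stop("recording contains non-finite values")
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec@data)
  if (n %% fs != 0L)
    stop("EDF writer requires a whole number of seconds (", n / fs, " s given)")
  nrec <- n %/% fs
  nch <- nrow(rec@data)
  if (is.null(physicalMax)) physicalMax <- max(1, ceiling(max(abs(rec@data))))
  if (max(abs(rec@data)) > physicalMax)
    stop("signal amplitude exceeds the declared physical range (+/-",
         physicalMax, " uV)")
  digMax <- 32767L; digMin <- -32767L
  scale <- (digMax - digMin) / (2 * physicalMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad(rec@subjectId, 80),
    .edfPad(paste0("eegstack group=", rec@group), 80),
    .edfPad("01.01.26", 8), .edfPad("00.00.00", 8),
    .edfPad(256L + 256L * nch, 8), .edfPad("", 44),
    .edfPad(nrec, 8), .edfPad(1L, 8), .edfPad(nch, 4)
  )
  fld <- function(values, width)
    paste(vapply(values, .edfPad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    fld(channelNames(rec), 16),
    fld(rep("", nch), 80),
    fld(rep("uV", nch), 8),
    fld(rep(-physicalMax, nch), 8),
    fld(rep(physicalMax, nch), 8),
    fld(rep(digMin, nch), 8),
    fld(rep(digMax, nch), 8),
    fld(rep("", nch), 80),
    fld(rep(fs, nch), 8),
    fld(rep("", nch), 32))
  writeChar(hdr, con, eos = NULL)
  dig <- matrix(as.integer(round((rec@data + physicalMax) * scale)) + digMin,
                nrow = nch)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' All signals are converted to microvolts using the declared physical
#' dimension (`uV`, `mV` or `V`; unknown dimensions are assumed uV).
#'
#' @param path EDF file path.
#' @param subjectId,group optional overrides; by default the subject id is
#'   the header's patient field and the group is `"unknown"`.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, subjectId = NULL, group = "unknown") {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)
  headerBytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1L) stop("malformed EDF header (signal count)")
  rdv <- function(width) vapply(seq_len(nch), function(i) rd(width), "")
  labels <- rdv(16); rdv(80)
  dims <- rdv(8)
  physMin <- as.numeric(rdv(8)); physMax <- as.numeric(rdv(8))
  digMin <- as.numeric(rdv(8)); digMax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (any(is.na(c(physMin, physMax, digMin, digMax, spr))))
    stop("malformed EDF signal headers")
  seek(con, headerBytes)
  total <- sum(spr)
  data <- matrix(0, nrow = nch, ncol = spr[1L] * nrec)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  for (r in seq_len(nrec)) {
    rec_vals <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                        endian = "little")
    if (length(rec_vals) < total) stop("EDF data truncated at record ", r)
    off <- 0L
    for (ch in seq_len(nch)) {
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        rec_vals[(off + 1L):(off + spr[ch])]
      off <- off + spr[ch]
    }
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  unit_scale <- vapply(tolower(dims), function(d)
    switch(d, "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1), 1)
  for (ch in seq_len(nch))
    data[ch, ] <- (data[ch, ] - digMin[ch]) * gain[ch] + physMin[ch]
  data <- data * unit_scale
  fs <- spr[1L] / recDur
  rownames(data) <- labels
  EEGRecording(data, fs = fs,
               subjectId = if (is.null(subjectId)) patient else subjectId,
               group = group)
}
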