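#' @include AllClasses.R regions-bands.R
NULL

# Bare 10-20 label from a dataset-dialect channel name: strips a leading
# "EEG " prefix and a reference suffix ("-LE", "-A1", ...), then maps
# case-insensitively onto the canonical 10-20 capitalization.
.bareChannelName <- function(name) {
  x <- sub("^\\s*EEG\\s+", "", name, ignore.case = TRUE)
  x <- sub("-[A-Za-z0-9]+$", "", x)
  x <- trimws(x)
  hit <- match(tolower(x), tolower(.STANDARD_1020))
  ifelse(is.na(hit), x, .STANDARD_1020[hit])
}

#' Drop irrelevant channels and standardize names to the 10-20 system
#'
#' Removes channels in `drop` (matched case-insensitively against raw
#' names), strips "EEG " prefixes and reference suffixes from the survivors
#' (e.g. `"EEG Fp1-LE"` becomes `"Fp1"`), applies any explicit `rename`
#' overrides, and preserves channel order. The signal itself is untouched.
#'
#' @param rec an [EEGRecording-class].
#' @param drop character vector of raw channel names to remove; the default
#'   removes the non-EEG bookkeeping channels found in the source dataset.
#' @param rename optional named character vector `c(raw = "NewName")`
#'   applied after the automatic cleanup.
#' @return the recording with standardized channels.
#' @examples
#' rec <- EEGRecording(matrix(0, 2, 8,
#'   dimnames = list(c("EEG Fp1-LE", "EEG A2-A1"), NULL)), fs = 256)
#' channelNames(standardizeChannels(rec))
#' @export
standardizeChannels <- function(rec,
                                drop = c("EEG A2-A1", "EEG 23A-23R", "EEG 24A-24R"),
                                rename = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  raw <- channelNames(rec)
  keep <- !(tolower(raw) %in% tolower(drop))
  if (!any(keep)) stop("all channels dropped; nothing left to analyse")
  data <- rec@data[keep, , drop = FALSE]
  nm <- .bareChannelName(raw[keep])
  if (!is.null(rename)) {
    hit <- match(raw[keep], names(rename))
    nm[!is.na(hit)] <- rename[hit[!is.na(hit)]]
  }
  if (anyDuplicated(nm))
    stop("channel standardization produced duplicate names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rownames(data) <- nm
  initialize(rec, data = data)
}
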