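#' @include AllClasses.R
NULL

# Standard 19-channel 10-20 montage, canonical capitalization.
.STANDARD_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                    "Fz", "Cz", "Pz")

#' Default scalp-region map
#'
#' Five regions partitioning the 19-channel 10-20 montage: Frontal
#' (Fp1, Fp2, F3, F4), Left Temporal (F7, T3, T5), Parietal-Occipital
#' (P3, P4, O1, O2), Right Temporal (F8, T4, T6) and Central
#' (C3, C4, Fz, Cz, Pz).
#'
#' @return named list of ordered channel-name vectors.
#' @examples
#' names(defaultRegionMap())
#' @export
defaultRegionMap <- function() {
  list(
    "Frontal"            = c("Fp1", "Fp2", "F3", "F4"),
    "Left Temporal"      = c("F7", "T3", "T5"),
    "Parietal-Occipital" = c("P3", "P4", "O1", "O2"),
    "Right Temporal"     = c("F8", "T4", "T6"),
    "Central"            = c("C3", "C4", "Fz", "Cz", "Pz")
  )
}

.validateRegionMap <- function(map) {
  stopifnot(is.list(map), length(map) >= 1L, !is.null(names(map)))
  all_ch <- unlist(map, use.names = FALSE)
  if (anyDuplicated(all_ch))
    stop("region map channel lists must be disjoint (duplicated: ",
         paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "), ")")
  invisible(map)
}

#' Channels belonging to one region
#'
#' @param map a region map (named list), e.g. [defaultRegionMap()].
#' @param region region name.
#' @return ordered character vector of channel names.
#' @examples
#' regionChannels(defaultRegionMap(), "Left Temporal")
#' @export
regionChannels <- function(map = defaultRegionMap(), region) {
  .validateRegionMap(map)
  if (!region %in% names(map))
    stop(sprintf("unknown region '%s'; valid regions: %s", region,
                 paste(names(map), collapse = ", ")))
  map[[region]]
}

#' Frequency-band schemes
#'
#' `"standard"` follows the six-band decomposition used throughout the
#' analysis: delta 0.5-4, theta 4-8, alpha 8-13, beta1 13-21, beta2 21-30,
#' gamma 30-48 Hz. `"table2"` is the narrower variant (delta 1-3, theta 4-7,
#' alpha 8-11, beta1 12-20, beta2 21-29, gamma 30-48 Hz) that leaves gaps
#' between bands.
#'
#' @param preset `"standard"` (default) or `"table2"`.
#' @return named list of `c(lo, hi)` band edges in Hz, ascending and
#'   non-overlapping.
#' @examples
#' bandScheme()$alpha
#' @export
bandScheme <- function(preset = c("standard", "table2")) {
  preset <- match.arg(preset)
  b <- switch(preset,
    standard = list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                    beta1 = c(13, 21), beta2 = c(21, 30), gamma = c(30, 48)),
    table2   = list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 11),
                    beta1 = c(12, 20), beta2 = c(21, 29), gamma = c(30, 48))
  )
  .validateBandScheme(b)
}

.validateBandScheme <- function(bands) {
  stopifnot(is.list(bands), !is.null(names(bands)))
  edges <- do.call(rbind, bands)
  if (any(edges[, 2L] <= edges[, 1L])) stop("band upper edge must exceed lower edge")
  if (is.unsorted(edges[, 1L], strictly = TRUE)) stop("bands must be in ascending order")
  if (any(edges[-1L, 1L] < edges[-nrow(edges), 2L]))
    stop("bands must not overlap")
  bands
}
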