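#' @include AllClasses.R selection.R
NULL

utils::globalVariables(c("region", "relative_power", "band", "group"))

#' Relative band-power group statistics
#'
#' For every region x band x group cell: the median, first and third
#' quartiles (linear-interpolation quantiles, R type 7) and the outlier
#' values beyond 1.5 IQR of the relative band power (band power divided
#' by the region's total power, both taken from the feature table), plus
#' a two-sided Mann-Whitney p-value for the group difference within each
#' region x band.
#'
#' @param ft a [FeatureTable-class] containing both groups.
#' @param regions region names to include (default: all in the table).
#' @param bands band names (default: the six standard bands).
#' @return list: `summary` (data.frame, one row per region x band x
#'   group), `tests` (data.frame, one row per region x band with the
#'   Mann-Whitney p), and `values` (long data.frame of relative powers,
#'   ready for plotting).
#' @export
bandPowerGroupReport <- function(ft, regions = NULL, bands = names(bandScheme())) {
  stopifnot(is(ft, "FeatureTable"))
  labs <- epochLabels(ft)
  if (length(unique(labs)) < 2L) stop("both groups must be present")
  allCols <- rownames(ft)
  if (is.null(regions))
    regions <- unique(sub("__.*$", "", allCols))
  X <- featureMatrix(ft)
  long <- list()
  for (r in regions) {
    tot <- X[, paste0(r, "__total_power")]
    for (b in bands) {
      col <- paste0(r, "__", b, "_power")
      if (!col %in% colnames(X)) stop("missing column ", col)
      long[[paste(r, b)]] <- data.frame(
        region = r, band = b, group = labs,
        relative_power = X[, col] / tot)
    }
  }
  values <- do.call(rbind, long)
  rownames(values) <- NULL
  q <- function(v, p) unname(quantile(v, p, type = 7))
  summary <- do.call(rbind, lapply(split(values, values[c("region", "band", "group")],
                                         drop = TRUE), function(d) {
    v <- d$relative_power
    q1 <- q(v, 0.25); q3 <- q(v, 0.75); iqr <- q3 - q1
    data.frame(region = d$region[1L], band = d$band[1L], group = d$group[1L],
               median = q(v, 0.5), q1 = q1, q3 = q3,
               n_outliers = sum(v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr),
               n = length(v))
  }))
  rownames(summary) <- NULL
  tests <- do.call(rbind, lapply(split(values, values[c("region", "band")],
                                       drop = TRUE), function(d) {
    p <- suppressWarnings(wilcox.test(
      d$relative_power[d$group == "MDD"],
      d$relative_power[d$group != "MDD"], exact = FALSE)$p.value)
    data.frame(region = d$region[1L], band = d$band[1L],
               p_value = if (is.nan(p)) 1 else p)
  }))
  rownames(tests) <- NULL
  list(summary = summary, tests = tests, values = values)
}

#' Grouped box plots of relative band power
#'
#' Renders the [bandPowerGroupReport()] values as box plots (median line,
#' quartile hinges, 1.5 IQR whiskers, outlier points), one panel per
#' band, regions on the horizontal axis, groups in colour.
#'
#' @param report the list returned by [bandPowerGroupReport()].
#' @return a ggplot object.
#' @export
plotBandPowers <- function(report) {
  v <- report$values
  ggplot2::ggplot(v, ggplot2::aes(x = region, y = relative_power,
                                  fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative band power", fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
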