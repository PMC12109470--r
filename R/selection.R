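#' @include AllClasses.R features.R
NULL

#' Route one feature to a parametric or non-parametric two-group test
#'
#' Shapiro-Wilk normality is assessed in each group and Levene's test
#' (median-centered, i.e. Brown-Forsythe) checks variance homogeneity.
#' If normality holds in BOTH groups and variances are homogeneous (all
#' gate p-values >= `gateAlpha`), a one-way two-group ANOVA is used;
#' otherwise a two-sided Mann-Whitney U test. A degenerate (constant)
#' group forces the Mann-Whitney branch.
#'
#' @param valuesMdd,valuesHc numeric feature values per group (>= 3 each).
#' @param gateAlpha level for the routing gates (default 0.05).
#' @return list: `test_used` (`"anova"` or `"mann_whitney"`), `raw_p`,
#'   `shapiro_p_mdd`, `shapiro_p_hc`, `levene_p`, `degenerate`.
#' @export
routeAndTest <- function(valuesMdd, valuesHc, gateAlpha = 0.05) {
  stopifnot(length(valuesMdd) >= 3L, length(valuesHc) >= 3L)
  degen <- var(valuesMdd) == 0 || var(valuesHc) == 0
  sw <- function(v) {
    if (var(v) == 0) return(0)
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }
  p_mdd <- sw(valuesMdd); p_hc <- sw(valuesHc)
  y <- c(valuesMdd, valuesHc)
  g <- factor(rep(c("MDD", "HC"), c(length(valuesMdd), length(valuesHc))))
  lev <- if (degen) 0 else
    car::leveneTest(y, g, center = median)[["Pr(>F)"]][1L]
  if (!degen && p_mdd >= gateAlpha && p_hc >= gateAlpha && lev >= gateAlpha) {
    raw_p <- anova(lm(y ~ g))[["Pr(>F)"]][1L]
    test <- "anova"
  } else {
    raw_p <- suppressWarnings(wilcox.test(valuesMdd, valuesHc,
                                          exact = FALSE)$p.value)
    if (is.nan(raw_p)) raw_p <- 1        # all values tied across both groups
    test <- "mann_whitney"
  }
  list(test_used = test, raw_p = raw_p, shapiro_p_mdd = p_mdd,
       shapiro_p_hc = p_hc, levene_p = lev, degenerate = degen)
}

#' Bonferroni adjustment
#'
#' `adjusted_i = min(1, m * p_i)` over the family of `m` p-values.
#'
#' @param rawP numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(rawP) {
  if (any(rawP < 0 | rawP > 1, na.rm = TRUE) || anyNA(rawP))
    stop("p-values must lie in [0, 1]")
  p.adjust(rawP, method = "bonferroni")
}

#' Significance-routed feature selection
#'
#' Applies [routeAndTest()] to every feature column, adjusts the raw
#' p-values over the whole family (Bonferroni by default; optional
#' Benjamini-Hochberg), and keeps features with adjusted p below `alpha`.
#' Selection can operate on epoch-level rows (each epoch a sample,
#' default) or on subject means to avoid pseudo-replication.
#'
#' @param ft a [FeatureTable-class] containing both groups.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param gateAlpha routing-gate level (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param level `"epoch"` (default) or `"subject"` (subject means).
#' @return list: `result` (a [SelectionResult-class]), `reduced` (the
#'   [FeatureTable-class] restricted to selected columns, in original
#'   order), `regionShares` (percentage of selected features contributed
#'   by each region).
#' @export
selectFeatures <- function(ft, alpha = 0.05, gateAlpha = 0.05,
                           adjust = c("bonferroni", "BH"),
                           level = c("epoch", "subject")) {
  adjust <- match.arg(adjust)
  level <- match.arg(level)
  stopifnot(is(ft, "FeatureTable"))
  X <- featureMatrix(ft)
  labs <- epochLabels(ft)
  if (level == "subject") {
    subs <- epochSubjects(ft)
    X <- do.call(rbind, lapply(split(seq_along(subs), subs), function(i)
      colMeans(X[i, , drop = FALSE])))
    labs <- vapply(split(labs, subs), `[`, "", 1L)[rownames(X)]
  }
  if (length(unique(labs)) < 2L)
    stop("feature selection requires both groups present")
  isM <- labs == "MDD"
  res <- lapply(seq_len(ncol(X)), function(j)
    routeAndTest(X[isM, j], X[!isM, j], gateAlpha))
  stats <- data.frame(
    feature       = colnames(X),
    shapiro_p_mdd = vapply(res, `[[`, 0, "shapiro_p_mdd"),
    shapiro_p_hc  = vapply(res, `[[`, 0, "shapiro_p_hc"),
    levene_p      = vapply(res, `[[`, 0, "levene_p"),
    test_used     = vapply(res, `[[`, "", "test_used"),
    raw_p         = vapply(res, `[[`, 0, "raw_p"),
    degenerate    = vapply(res, `[[`, TRUE, "degenerate"),
    stringsAsFactors = FALSE
  )
  stats$adjusted_p <- if (adjust == "bonferroni")
    bonferroniAdjust(stats$raw_p) else p.adjust(stats$raw_p, "BH")
  # alpha = 1 is the vacuous threshold: everything passes even though
  # adjusted p-values are capped at exactly 1
  stats$selected <- if (alpha >= 1) rep(TRUE, nrow(stats)) else
    stats$adjusted_p < alpha
  sel <- new("SelectionResult", stats = stats, alpha = alpha,
             gateAlpha = gateAlpha, adjust = adjust,
             nTested = ncol(X))
  keep <- stats$feature[stats$selected]
  reduced <- ft[match(keep, rownames(ft)), ]
  region <- sub("__.*$", "", keep)
  shares <- if (length(keep))
    100 * table(region) / length(keep) else table(character())
  list(result = sel, reduced = reduced, regionShares = shares)
}
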