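#' Fixed-effect (inverse-variance) pooling
#'
#' Weights `w_i = 1 / se_i^2`; pooled estimate `sum(w * theta) / sum(w)`
#' with standard error `1 / sqrt(sum(w))`.
#'
#' @param estimates,ses Equal-length numeric vectors; `ses` positive.
#' @return A list with `pooled` and `pooled_se`.
#' @export
fixed_effect_pool <- function(estimates, ses) {
  if (!length(estimates)) stop("empty input")
  stopifnot(length(estimates) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  list(pooled = sum(w * estimates) / sum(w), pooled_se = 1 / sqrt(sum(w)))
}

#' Between-group heterogeneity of a fixed-effect meta-analysis
#'
#' Pools each group by inverse variance, then tests whether group-level
#' pooled estimates differ: `Q_between = sum_g W_g * (theta_g - theta_all)^2`
#' with `W_g` the summed weights in group `g` and `theta_all` the
#' fixed-effect pool of all rows. `I2 = max(0, (Q - df) / Q)` and the
#' p-value comes from the chi-square upper tail with `df = #groups - 1`.
#' Rows with missing standard errors are excluded and counted in
#' `n_excluded` (the trait whose SE the fit could not deliver never enters
#' a comparison).
#'
#' @param rows Data frame with columns `trait`, `group`, `estimate`, `se`.
#' @param groups Optional character vector naming the groups to compare
#'   (default: all groups present, in order of appearance).
#' @return A one-row tibble of class `meta_result`: group labels, pooled
#'   estimates and SEs, `Q_between`, `df`, `I2`, `p`, `n_traits_used`,
#'   `n_excluded`, `excluded_traits`.
#' @export
between_group_heterogeneity <- function(rows, groups = NULL) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("group", "estimate", "se") %in% names(rows)))
  if (!"trait" %in% names(rows)) rows$trait <- as.character(seq_len(nrow(rows)))
  groups <- groups %||% unique(rows$group)
  rows <- rows[rows$group %in% groups, , drop = FALSE]
  usable <- !is.na(rows$se) & rows$se > 0 & !is.na(rows$estimate)
  excluded <- rows$trait[!usable]
  rows <- rows[usable, , drop = FALSE]
  for (g in groups) if (!any(rows$group == g))
    stop("group has no usable rows: ", g)

  pools <- lapply(groups, function(g) {
    sub <- rows[rows$group == g, ]
    c(fixed_effect_pool(sub$estimate, sub$se), list(k = nrow(sub)))
  })
  all_pool <- fixed_effect_pool(rows$estimate, rows$se)
  Wg <- vapply(pools, function(p) 1 / p$pooled_se^2, numeric(1))
  tg <- vapply(pools, function(p) p$pooled, numeric(1))
  Q <- sum(Wg * (tg - all_pool$pooled)^2)
  df <- length(groups) - 1L
  I2 <- if (Q > df) (Q - df) / Q else 0
  p <- pchisq(Q, df, lower.tail = FALSE)
  out <- tibble::tibble(
    group1 = groups[1],
    group2 = if (length(groups) > 1) groups[2] else NA_character_,
    pooled1 = tg[1], se1 = 1 / sqrt(Wg[1]),
    pooled2 = if (length(groups) > 1) tg[2] else NA_real_,
    se2 = if (length(groups) > 1) 1 / sqrt(Wg[2]) else NA_real_,
    Q_between = Q, df = df, I2 = I2, p = p,
    n_traits_used = nrow(rows), n_excluded = length(excluded),
    excluded_traits = paste(excluded, collapse = ";"))
  class(out) <- c("meta_result", class(out))
  out
}

#' Within-group heterogeneity (I-squared across traits of one group)
#'
#' Cochran's Q of individual traits around their fixed-effect pool:
#' `Q = sum(w_i * (theta_i - pooled)^2)`, `df = k - 1`,
#' `I2 = max(0, (Q - df) / Q)`.
#'
#' @param estimates,ses Trait-level estimates and positive SEs.
#' @return A list with `Q`, `df`, `I2`, `p`, `k`.
#' @export
within_group_heterogeneity <- function(estimates, ses) {
  pool <- fixed_effect_pool(estimates, ses)
  w <- 1 / ses^2
  Q <- sum(w * (estimates - pool$pooled)^2)
  df <- length(estimates) - 1L
  I2 <- if (Q > df) (Q - df) / Q else 0
  list(Q = Q, df = df, I2 = I2,
       p = pchisq(Q, df, lower.tail = FALSE), k = length(estimates))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the supplied family.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, nonzero variance.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_corr_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric enumeration with the point-probability definition of
#' two-sidedness: the p-value sums probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table. Any zero margin yields p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Welch's unequal-variance t test
#'
#' @param x,y Numeric samples of length at least 2 each.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both samples")
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Heterogeneity comparisons across a configured family of group pairs
#'
#' Runs [between_group_heterogeneity()] for each configured pair of trait
#' groups on one metric column and applies BH-FDR across exactly that
#' family of tests.
#'
#' @param metrics Data frame with columns `trait`, `group`, the metric
#'   column, and its SE column.
#' @param pairs List of length-2 character vectors of group labels.
#' @param estimate_col,se_col Names of the metric and SE columns.
#' @return A tibble with one row per pair: pair labels, pooled estimates,
#'   `Q_between`, `df`, `I2`, `p`, `fdr`, `n_traits_used`, `n_excluded`.
#' @export
compare_groups <- function(metrics, pairs, estimate_col = "estimate",
                           se_col = "se") {
  stopifnot(length(pairs) >= 1)
  metrics <- tibble::as_tibble(metrics)
  rows <- tibble::tibble(trait = metrics$trait, group = metrics$group,
                         estimate = metrics[[estimate_col]],
                         se = metrics[[se_col]])
  res <- dplyr::bind_rows(lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    between_group_heterogeneity(rows, groups = pr)
  }))
  res$fdr <- bh_fdr(res$p)
  res
}

#' Forest-plot data for one metric
#'
#' Per-trait estimates with 95% intervals plus one pooled "diamond" row per
#' group, as a tidy table ready for plotting.
#'
#' @param metrics Data frame with `trait`, `group`, the metric and SE
#'   columns.
#' @param estimate_col,se_col Column names.
#' @return A tibble with columns `label`, `group`, `estimate`, `lo`, `hi`,
#'   `is_pooled`.
#' @export
forest_data <- function(metrics, estimate_col = "estimate", se_col = "se") {
  metrics <- tibble::as_tibble(metrics)
  est <- metrics[[estimate_col]]; se <- metrics[[se_col]]
  keep <- !is.na(se) & se > 0
  rows <- tibble::tibble(label = metrics$trait[keep],
                         group = metrics$group[keep],
                         estimate = est[keep],
                         lo = est[keep] - 1.96 * se[keep],
                         hi = est[keep] + 1.96 * se[keep],
                         is_pooled = FALSE)
  pooled <- dplyr::bind_rows(lapply(unique(rows$group), function(g) {
    sub <- rows[rows$group == g, ]
    pl <- fixed_effect_pool(sub$estimate, (sub$hi - sub$lo) / (2 * 1.96))
    tibble::tibble(label = paste0(g, " (pooled)"), group = g,
                   estimate = pl$pooled,
                   lo = pl$pooled - 1.96 * pl$pooled_se,
                   hi = pl$pooled + 1.96 * pl$pooled_se,
                   is_pooled = TRUE)
  }))
  dplyr::bind_rows(rows, pooled)
}
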