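#' Predicted number of susceptibility SNPs
#'
#' Polygenicity point estimate `pi_c * M` with a 95% confidence interval
#' obtained by plugging `pi_c +/- 1.96 * se_pi` into the same product; the
#' lower limit is clamped at zero. An unavailable standard error (e.g. a
#' fit whose Hessian was singular) yields a point estimate with an
#' unavailable interval.
#'
#' @param pi_c Proportion of reference SNPs that are sSNPs.
#' @param se_pi Standard error of `pi_c`, or `NA` when unavailable.
#' @param M Reference-panel SNP count.
#' @return A list of class `polygenicity_estimate`: `pi_c`, `se_pi`,
#'   `n_ssnp`, `ci95` (length-2 or `NULL`).
#' @export
n_ssnps <- function(pi_c, se_pi = NA_real_, M) {
  stopifnot(is_fraction(pi_c), M > 0)
  ci <- if (is.na(se_pi)) NULL
        else c(max(pi_c - 1.96 * se_pi, 0) * M, (pi_c + 1.96 * se_pi) * M)
  structure(list(pi_c = pi_c, se_pi = se_pi, n_ssnp = pi_c * M, ci95 = ci),
            class = "polygenicity_estimate")
}

#' Number of sSNPs in the larger-variance cluster of an M3 fit
#'
#' @param pi_c Overall sSNP proportion.
#' @param prop Fraction of sSNPs in the larger-variance cluster.
#' @param M Reference-panel SNP count.
#' @return `pi_c * prop * M`.
#' @export
n_ssnps_cluster1 <- function(pi_c, prop, M) {
  stopifnot(is_fraction(pi_c), is_fraction(prop, open_lo = FALSE, open_hi = FALSE),
            M > 0)
  pi_c * prop * M
}

#' Median absolute sSNP effect under a single normal component
#'
#' For effects `beta ~ N(0, sigma2)`, the median of `|beta|` is the upper
#' quartile of the normal: the `x >= 0` with `P(N(0, sigma2) > x) = 0.25`.
#'
#' @param sigma2 Effect-size variance (standardized scale).
#' @return Median absolute effect (0 when `sigma2 = 0`).
#' @export
median_abs_effect_m2 <- function(sigma2) {
  stopifnot(sigma2 >= 0)
  if (sigma2 == 0) return(0)
  qnorm(0.25, sd = sqrt(sigma2), lower.tail = FALSE)
}

#' Median absolute sSNP effect under a two-normal mixture
#'
#' Grid search for the smallest `x` with
#' `2 * (prop * P(N(0, sigma2_1) > x) + (1 - prop) * P(N(0, sigma2_2) > x)) < 0.5`,
#' i.e. the median of the absolute effect under the mixture. The default
#' grid is 200 evenly spaced values on `[0, 0.02]`. When no grid value
#' satisfies the inequality the result is `NA` with attribute
#' `exceeds_grid = TRUE`. `method = "bisect"` solves the same condition
#' continuously and agrees with the grid answer to within one grid step.
#'
#' @param prop Fraction of sSNPs in component 1 (the larger variance).
#' @param sigma2_1,sigma2_2 Component variances, `sigma2_1 >= sigma2_2`.
#' @param grid Candidate values (default `seq(0, 0.02, length.out = 200)`).
#' @param method `"grid"` (default) or `"bisect"`.
#' @return Median absolute effect; `NA` (attribute `exceeds_grid`) if it
#'   lies beyond the grid ceiling.
#' @export
median_abs_effect_m3 <- function(prop, sigma2_1, sigma2_2,
                                 grid = seq(0, 0.02, length.out = 200),
                                 method = c("grid", "bisect")) {
  method <- match.arg(method)
  stopifnot(sigma2_1 >= sigma2_2, sigma2_2 >= 0,
            is_fraction(prop, open_lo = FALSE, open_hi = FALSE))
  if (!length(grid)) stop("empty grid")
  tail2 <- function(x) {
    # upper tail of each component; sd = 0 collapses to a point mass at 0
    t1 <- if (sigma2_1 > 0) pnorm(x, sd = sqrt(sigma2_1), lower.tail = FALSE) else 0
    t2 <- if (sigma2_2 > 0) pnorm(x, sd = sqrt(sigma2_2), lower.tail = FALSE) else 0
    2 * (prop * t1 + (1 - prop) * t2)
  }
  if (method == "grid") {
    ok <- tail2(grid) < 0.5
    if (!any(ok))
      return(structure(NA_real_, exceeds_grid = TRUE))
    grid[which(ok)[1]]
  } else {
    if (tail2(0) < 0.5) return(0)
    hi <- max(grid)
    if (tail2(hi) >= 0.5)
      return(structure(NA_real_, exceeds_grid = TRUE))
    uniroot(function(x) tail2(x) - 0.5, c(0, hi), tol = 1e-12)$root
  }
}

#' Median absolute sSNP effect of a fitted model
#'
#' Dispatches to [median_abs_effect_m2()] or [median_abs_effect_m3()]
#' according to the parameter kind.
#'
#' @param params A [mixture_params()] (or a `mixture_fit`, whose parameters
#'   are used).
#' @param ... Passed to the M3 grid search.
#' @return Median absolute effect.
#' @export
median_abs_effect <- function(params, ...) {
  if (inherits(params, "mixture_fit")) params <- params$params
  stopifnot(inherits(params, "mixture_params"))
  if (params$kind == "M2") median_abs_effect_m2(params$sigma2)
  else median_abs_effect_m3(params$prop, params$sigma2_1, params$sigma2_2, ...)
}

#' Discoverability estimate with plug-in confidence interval
#'
#' Computes the median absolute sSNP effect at the fitted parameters and a
#' 95% interval by plugging `estimate +/- 1.96 * SE` endpoints of each
#' parameter entering the quantile formula into it. Out-of-range endpoints
#' are clamped: a negative variance lower bound becomes 0
#' (`sigma_lo_clamped`); a negative lower bound for `prop` becomes 0, i.e.
#' all sSNPs assigned to the smaller-variance cluster (`prop_lo_clamped`);
#' a `prop` upper bound above 1 becomes 1 (`prop_hi_clamped`). The lower
#' (upper) interval limit evaluates the metric at all lower (upper)
#' endpoints, which bounds the metric because it is nondecreasing in each
#' variance and, given `sigma2_1 >= sigma2_2`, in `prop`.
#'
#' @param fit A `mixture_fit`.
#' @param ... Passed to the M3 grid search.
#' @return A list of class `discoverability_estimate`: `median_abs_effect`,
#'   `ci95` (or `NULL` when SEs are unavailable), `clamp_flags`,
#'   `exceeds_grid`.
#' @export
discoverability_ci <- function(fit, ...) {
  stopifnot(inherits(fit, "mixture_fit"))
  p <- fit$params
  point <- median_abs_effect(p, ...)
  flags <- character(0)
  if (!fit$se_available) {
    return(structure(list(median_abs_effect = as.numeric(point), ci95 = NULL,
                          clamp_flags = flags,
                          exceeds_grid = isTRUE(attr(point, "exceeds_grid"))),
                     class = "discoverability_estimate"))
  }
  se <- fit$se
  if (p$kind == "M2") {
    lo_s <- p$sigma2 - 1.96 * se[["sigma2"]]
    hi_s <- p$sigma2 + 1.96 * se[["sigma2"]]
    if (lo_s < 0) { lo_s <- 0; flags <- c(flags, "sigma_lo_clamped") }
    ci <- c(median_abs_effect_m2(lo_s), median_abs_effect_m2(hi_s))
  } else {
    lo1 <- p$sigma2_1 - 1.96 * se[["sigma2_1"]]
    lo2 <- p$sigma2_2 - 1.96 * se[["sigma2_2"]]
    if (lo1 < 0 || lo2 < 0) flags <- c(flags, "sigma_lo_clamped")
    lo1 <- max(lo1, 0); lo2 <- max(lo2, 0)
    hi1 <- p$sigma2_1 + 1.96 * se[["sigma2_1"]]
    hi2 <- p$sigma2_2 + 1.96 * se[["sigma2_2"]]
    lo_p <- p$prop - 1.96 * se[["prop"]]
    hi_p <- p$prop + 1.96 * se[["prop"]]
    if (lo_p < 0) { lo_p <- 0; flags <- c(flags, "prop_lo_clamped") }
    if (hi_p > 1) { hi_p <- 1; flags <- c(flags, "prop_hi_clamped") }
    # keep the component ordering valid at the endpoints
    lo <- median_abs_effect_m3(lo_p, max(lo1, lo2), min(lo1, lo2), ...)
    hi <- median_abs_effect_m3(min(hi_p, 1), max(hi1, hi2), min(hi1, hi2), ...)
    ci <- c(lo, hi)
  }
  structure(list(median_abs_effect = as.numeric(point),
                 ci95 = as.numeric(ci), clamp_flags = flags,
                 exceeds_grid = isTRUE(attr(point, "exceeds_grid"))),
            class = "discoverability_estimate")
}

#' Model-implied SNP heritability
#'
#' The total genetic variance implied by the mixture on the standardized
#' scale: `h2 = M * pi_c * E[beta^2]`, with `E[beta^2] = sigma2` for M2 and
#' `prop * sigma2_1 + (1 - prop) * sigma2_2` for M3. The standard error is
#' a delta-method propagation of the parameter covariance when available.
#' Values above 1 indicate model misspecification and are flagged, not
#' truncated.
#'
#' @param fit A `mixture_fit`.
#' @param M Reference-panel SNP count; defaults to the fit's `M_reference`.
#' @return A list of class `heritability_estimate`: `h2`, `se_h2`,
#'   `warning_h2_gt_1`.
#' @export
heritability <- function(fit, M = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  M <- M %||% fit$M_reference
  p <- fit$params
  if (p$kind == "M2") {
    eb2 <- p$sigma2
    grad <- c(pi_c = M * p$sigma2, sigma2 = M * p$pi_c)
  } else {
    eb2 <- p$prop * p$sigma2_1 + (1 - p$prop) * p$sigma2_2
    grad <- c(pi_c = M * eb2,
              sigma2_1 = M * p$pi_c * p$prop,
              sigma2_2 = M * p$pi_c * (1 - p$prop),
              prop = M * p$pi_c * (p$sigma2_1 - p$sigma2_2))
  }
  h2 <- M * p$pi_c * eb2
  se_h2 <- NA_real_
  if (fit$se_available && !is.null(fit$covariance)) {
    nm <- intersect(names(grad), colnames(fit$covariance))
    g <- grad[nm]
    se_h2 <- sqrt(drop(t(g) %*% fit$covariance[nm, nm, drop = FALSE] %*% g))
  }
  if (h2 > 1)
    warning("model-implied heritability exceeds 1 (misspecification?)")
  structure(list(h2 = h2, se_h2 = se_h2, warning_h2_gt_1 = h2 > 1),
            class = "heritability_estimate")
}

#' One-row architecture summary of a fitted trait
#'
#' Combines polygenicity, discoverability and heritability (with their
#' intervals and flags) into a single tidy row for roster-level tables.
#'
#' @param fit A `mixture_fit`.
#' @param trait,group Labels carried into the row.
#' @param M Reference-panel SNP count; defaults to the fit's `M_reference`.
#' @return A one-row tibble.
#' @export
architecture_metrics <- function(fit, trait = NA_character_,
                                 group = NA_character_, M = NULL) {
  M <- M %||% fit$M_reference
  p <- fit$params
  se_pi <- if (fit$se_available) fit$se[["pi_c"]] else NA_real_
  poly <- n_ssnps(p$pi_c, se_pi, M)
  disc <- discoverability_ci(fit)
  disc_se <- if (fit$se_available && !is.null(disc$ci95))
    (disc$ci95[2] - disc$ci95[1]) / (2 * 1.96) else NA_real_
  her <- withCallingHandlers(heritability(fit, M),
                             warning = function(w) invokeRestart("muffleWarning"))
  tibble::tibble(
    trait = trait, group = group, model = p$kind,
    pi_c = p$pi_c, se_pi = se_pi,
    n_ssnp = poly$n_ssnp,
    n_ssnp_lo = if (is.null(poly$ci95)) NA_real_ else poly$ci95[1],
    n_ssnp_hi = if (is.null(poly$ci95)) NA_real_ else poly$ci95[2],
    n_ssnp_cluster1 = if (p$kind == "M3")
      n_ssnps_cluster1(p$pi_c, p$prop, M) else NA_real_,
    median_abs_effect = disc$median_abs_effect,
    mae_lo = if (is.null(disc$ci95)) NA_real_ else disc$ci95[1],
    mae_hi = if (is.null(disc$ci95)) NA_real_ else disc$ci95[2],
    mae_se = disc_se,
    clamp_flags = paste(disc$clamp_flags, collapse = ";"),
    h2 = her$h2, se_h2 = her$se_h2,
    se_available = fit$se_available, converged = fit$converged)
}
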