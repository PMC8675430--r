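#' Power to reach genome-wide significance
#'
#' Two-sided power of the z-test for a standardized effect `beta` at sample
#' size `n` and significance level `alpha`: with `z_t` the upper-tail
#' normal quantile at `alpha / 2`,
#' `power = P(Z > z_t - sqrt(n) * beta) + P(Z > z_t + sqrt(n) * beta)`.
#' At `beta = 0` this equals `alpha` exactly.
#'
#' @param beta Standardized effect size(s).
#' @param n Sample size(s), positive.
#' @param alpha Significance threshold (default 5e-8, genome-wide).
#' @return Power in `[alpha, 1]`, vectorized over `beta` and `n`.
#' @export
power_gws <- function(beta, n, alpha = 5e-8) {
  stopifnot(all(n > 0), is_fraction(alpha))
  zt <- qnorm(alpha / 2, lower.tail = FALSE)
  s <- sqrt(n) * beta
  out <- pnorm(zt - s, lower.tail = FALSE) + pnorm(zt + s, lower.tail = FALSE)
  # at beta = 0 the power is the size of the test by definition; return it
  # exactly rather than through the qnorm/pnorm round trip
  out[s == 0] <- alpha
  out
}

# Gauss-Hermite nodes/weights cached per node count
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(nodes)
  gh_cache[[key]]
}

# E[beta^2 * power(beta, n)] for beta ~ N(0, sigma2), by Gauss-Hermite:
# beta = sqrt(2 * sigma2) * x, weight w / sqrt(pi)
gh_second_moment_power <- function(sigma2, n, alpha, nodes) {
  if (sigma2 == 0) return(0)
  gh <- gh_rule(nodes)
  b <- sqrt(2 * sigma2) * gh$x
  sum(gh$w * b^2 * power_gws(b, n, alpha)) / sqrt(pi)
}

#' Percentage of heritability explained by genome-wide-significant SNPs
#'
#' `100 * E[beta^2 * power(beta, n)] / E[beta^2]`, expectations over the
#' sSNP effect distribution (a single normal for M2, the prop-weighted
#' two-normal mixture for M3), evaluated by Gauss-Hermite quadrature. The
#' projection assumes unit residual variance for the future study (no
#' stratification inflation), so the fitted intercept does not enter.
#'
#' @param params A [mixture_params()] (or a `mixture_fit`).
#' @param n Sample size(s) of the projected GWAS.
#' @param alpha Significance threshold (default 5e-8).
#' @param nodes Quadrature nodes per component (default 201; minimum 61).
#'   The GWS power curve is a steep sigmoid in the effect size, so a dense
#'   rule is needed for sub-0.1-point accuracy across the sample-size grid.
#' @return GV percentage in `[100 * alpha, 100]`, vectorized over `n`.
#' @export
gv_percentage <- function(params, n, alpha = 5e-8, nodes = 201) {
  if (inherits(params, "mixture_fit")) params <- params$params
  stopifnot(inherits(params, "mixture_params"), nodes >= 61)
  comp <- if (params$kind == "M2")
    list(w = 1, s2 = params$sigma2)
  else
    list(w = c(params$prop, 1 - params$prop),
         s2 = c(params$sigma2_1, params$sigma2_2))
  eb2 <- sum(comp$w * comp$s2)
  if (eb2 == 0) stop("effect-size distribution has zero variance")
  gv <- vapply(n, function(ni) {
    num <- sum(vapply(seq_along(comp$w), function(k)
      comp$w[k] * gh_second_moment_power(comp$s2[k], ni, alpha, nodes),
      numeric(1)))
    100 * num / eb2
  }, numeric(1))
  pmin(pmax(gv, 0), 100)  # guard quadrature round-off at the saturated end
}

#' Sample size required for GWS SNPs to explain a heritability threshold
#'
#' Evaluates [gv_percentage()] over a sample-size grid (default 50,000 to
#' 200,000,000 in steps of 50,000) and returns the smallest grid point at
#' which the GV percentage reaches `threshold` (default 99). When the
#' threshold is not reached by the end of the grid, the result is censored
#' and the GV percentage achieved at the maximum grid size is reported
#' instead. Because GV% is nondecreasing in `n`, evaluation stops at the
#' first grid point that passes (`early_exit = FALSE` forces a full-grid
#' sweep; the answer is identical).
#'
#' @param params A [mixture_params()] (or a `mixture_fit`).
#' @param grid_start,grid_end,step Sample-size grid (defaults 5e4, 2e8, 5e4).
#' @param threshold GV percentage to reach (default 99).
#' @param alpha Significance threshold (default 5e-8).
#' @param nodes Quadrature nodes (default 201).
#' @param early_exit Stop at the first passing grid point (default TRUE)?
#' @return A list of class `projection_curve`: `n_grid` and `gv_percent`
#'   (the evaluated prefix of the grid), `n_required` (`NA` when censored),
#'   `censored`, `gv_at_max` (GV% at `grid_end`, reported when censored),
#'   `threshold`, `alpha`.
#' @export
required_n <- function(params, grid_start = 5e4, grid_end = 2e8, step = 5e4,
                       threshold = 99, alpha = 5e-8, nodes = 201,
                       early_exit = TRUE) {
  if (inherits(params, "mixture_fit")) params <- params$params
  stopifnot(grid_start > 0, grid_end >= grid_start, step > 0,
            threshold > 0, threshold <= 100)
  grid <- seq(grid_start, grid_end, by = step)
  gv <- numeric(0)
  n_req <- NA_real_
  if (early_exit) {
    for (i in seq_along(grid)) {
      gv[i] <- gv_percentage(params, grid[i], alpha, nodes)
      if (gv[i] >= threshold) { n_req <- grid[i]; break }
    }
    grid <- grid[seq_along(gv)]
  } else {
    gv <- gv_percentage(params, grid, alpha, nodes)
    pass <- which(gv >= threshold)
    if (length(pass)) n_req <- grid[pass[1]]
  }
  censored <- is.na(n_req)
  gv_at_max <- if (censored)
    gv_percentage(params, grid_end, alpha, nodes) else NA_real_
  structure(list(n_grid = grid, gv_percent = gv,
                 n_required = n_req, censored = censored,
                 gv_at_max = gv_at_max,
                 threshold = threshold, alpha = alpha),
            class = "projection_curve")
}

#' @export
print.projection_curve <- function(x, ...) {
  if (x$censored)
    cat(sprintf("GV%% does not reach %g%% by n = %g (GV%% at max = %.2f)\n",
                x$threshold, max(x$n_grid), x$gv_at_max))
  else
    cat(sprintf("n required for GV%% >= %g%%: %g\n", x$threshold, x$n_required))
  invisible(x)
}

#' Tidy table of a projection curve
#'
#' @param curve A `projection_curve`.
#' @param trait Optional trait label column.
#' @return A tibble with columns `trait`, `n`, `gv_percent`.
#' @export
projection_table <- function(curve, trait = NA_character_) {
  tibble::tibble(trait = trait, n = curve$n_grid, gv_percent = curve$gv_percent)
}
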