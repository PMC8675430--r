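test_that("sSNP counts scale pi_c by M with clamped plug-in intervals", {
  expect_equal(n_ssnps(0.5, NA_real_, 1e6)$n_ssnp, 5e5)
  est <- n_ssnps(0.009292, 0.00162, 1070777)
  expect_equal(est$n_ssnp, 0.009292 * 1070777)
  expect_equal(est$n_ssnp, 9949.7, tolerance = 1e-4)
  # interval width is exactly 2 * 1.96 * se * M before clamping
  expect_equal(diff(est$ci95), 2 * 1.96 * 0.00162 * 1070777)
  # unavailable SE: point only
  expect_null(n_ssnps(0.01, NA_real_, 1e6)$ci95)
  # lower clamp at zero
  lo <- n_ssnps(0.001, 0.01, 1e6)
  expect_equal(lo$ci95[1], 0)
})

test_that("cluster-1 sSNP count is the prop-weighted share", {
  expect_equal(n_ssnps_cluster1(0.01, 1, 1e6), n_ssnps(0.01, NA, 1e6)$n_ssnp)
  expect_equal(n_ssnps_cluster1(0.01, 0, 1e6), 0)
  expect_equal(n_ssnps_cluster1(0.01, 0.3, 1e6), 3000)
})

test_that("single-component median absolute effect is the upper quartile", {
  expect_equal(median_abs_effect_m2(0), 0)
  expect_equal(median_abs_effect_m2(1), 0.6744898, tolerance = 1e-6)
  # scale family: result(c * s2) = sqrt(c) * result(s2)
  for (cc in c(0.25, 4, 9)) {
    expect_equal(median_abs_effect_m2(cc * 3e-5),
                 sqrt(cc) * median_abs_effect_m2(3e-5))
  }
})

test_that("mixture median matches the single-component form in degenerate cases", {
  step <- 0.02 / 199
  expect_lte(abs(median_abs_effect_m3(1, 4e-5, 1e-6) -
                   median_abs_effect_m2(4e-5)), step)
  s <- 2e-5
  expect_lte(abs(median_abs_effect_m3(0.6, s, s) - median_abs_effect_m2(s)),
             step)
  expect_error(median_abs_effect_m3(0.5, 1e-5, 1e-6, grid = numeric(0)),
               "empty grid")
})

test_that("grid search agrees with a large Monte-Carlo sample of |beta|", {
  step <- 0.02 / 199
  mc_median <- function(prop, s1, s2, n = 1e6) {
    withr::with_seed(404, {
      comp <- runif(n) < prop
      abs(rnorm(n, 0, ifelse(comp, sqrt(s1), sqrt(s2)))) |> median()
    })
  }
  expect_lte(abs(median_abs_effect_m3(0.4, 4e-5, 1e-6) -
                   mc_median(0.4, 4e-5, 1e-6)), step)
  # bisect mode agrees with the grid within one step
  g <- median_abs_effect_m3(0.4, 4e-5, 1e-6)
  b <- median_abs_effect_m3(0.4, 4e-5, 1e-6, method = "bisect")
  expect_lte(abs(g - b), step)
})

test_that("mixture median is monotone in each variance and in prop", {
  base <- median_abs_effect_m3(0.5, 2e-5, 5e-6, method = "bisect")
  expect_gte(median_abs_effect_m3(0.5, 4e-5, 5e-6, method = "bisect"), base)
  expect_gte(median_abs_effect_m3(0.5, 2e-5, 9e-6, method = "bisect"), base)
  expect_gte(median_abs_effect_m3(0.7, 2e-5, 5e-6, method = "bisect"), base)
})

test_that("a median beyond the grid ceiling is flagged, not extrapolated", {
  res <- median_abs_effect_m3(0.9, 0.01, 0.005)  # median |beta| ~ 0.09 > 0.02
  expect_true(is.na(res))
  expect_true(attr(res, "exceeds_grid"))
})

mk_fit <- function(params, se = NULL, covariance = NULL) {
  structure(list(params = params, se = se, covariance = covariance,
                 se_available = !is.null(se), converged = TRUE,
                 M_reference = 1e6, intercept_mode = "estimate"),
            class = "mixture_fit")
}

test_that("discoverability CI plugs clamped endpoints into the quantile", {
  p2 <- mixture_params("M2", pi_c = 0.01, sigma2 = 4e-5)
  # zero SEs: degenerate interval at the point
  d0 <- discoverability_ci(mk_fit(p2, se = c(pi_c = 0, sigma2 = 0,
                                             intercept_a = 0)))
  expect_equal(d0$ci95[1], d0$median_abs_effect)
  expect_equal(d0$ci95[2], d0$median_abs_effect)
  expect_length(d0$clamp_flags, 0)
  # sigma lower endpoint below zero is clamped and flagged
  dc <- discoverability_ci(mk_fit(
    mixture_params("M2", pi_c = 0.01, sigma2 = 1e-6),
    se = c(pi_c = 1e-3, sigma2 = 1e-6, intercept_a = 0.01)))
  expect_true("sigma_lo_clamped" %in% dc$clamp_flags)
  expect_equal(dc$ci95[1], 0)
  # prop upper endpoint above one is clamped and flagged
  p3 <- mixture_params("M3", pi_c = 0.01, sigma2_1 = 4e-5, sigma2_2 = 1e-6,
                       prop = 0.9)
  d3 <- discoverability_ci(mk_fit(
    p3, se = c(pi_c = 1e-3, sigma2_1 = 5e-6, sigma2_2 = 5e-7,
               prop = 0.1, intercept_a = 0.01)))
  expect_true("prop_hi_clamped" %in% d3$clamp_flags)
  # prop lower endpoint below zero: all sSNPs treated as cluster 2
  d3b <- discoverability_ci(mk_fit(
    mixture_params("M3", pi_c = 0.01, sigma2_1 = 4e-5, sigma2_2 = 1e-6,
                   prop = 0.1),
    se = c(pi_c = 1e-3, sigma2_1 = 5e-6, sigma2_2 = 5e-7,
           prop = 0.1, intercept_a = 0.01)))
  expect_true("prop_lo_clamped" %in% d3b$clamp_flags)
  # the interval contains the point whenever nothing clamped
  dok <- discoverability_ci(mk_fit(
    p2, se = c(pi_c = 1e-3, sigma2 = 5e-6, intercept_a = 0.01)))
  expect_length(dok$clamp_flags, 0)
  expect_lte(dok$ci95[1], dok$median_abs_effect)
  expect_gte(dok$ci95[2], dok$median_abs_effect)
  # unavailable SEs: point only
  expect_null(discoverability_ci(mk_fit(p2))$ci95)
})

test_that("heritability is the model-implied genetic variance", {
  f2 <- mk_fit(mixture_params("M2", pi_c = 0.01, sigma2 = 1e-5))
  expect_equal(heritability(f2, M = 1e6)$h2, 0.1)
  f3 <- mk_fit(mixture_params("M3", pi_c = 0.01, sigma2_1 = 1e-5,
                              sigma2_2 = 1e-5, prop = 0.5))
  expect_equal(heritability(f3, M = 1e6)$h2, 0.1)
  big <- mk_fit(mixture_params("M2", pi_c = 0.4, sigma2 = 1e-5))
  expect_warning(h <- heritability(big, M = 1e6), "exceeds 1")
  expect_true(h$warning_h2_gt_1)
  expect_equal(h$h2, 4)
})

test_that("heritability estimate tracks the generator's realized sum of beta^2", {
  rel_err <- vapply(1:5, function(s) {
    sim <- sim_m2_quick(seed = s, M = 40000, pi_c = 0.01, sigma2 = 2e-4)
    fit <- fit_mixture(sim$table, "M2", se = FALSE)
    heritability(fit)$h2 / sim$realized_h2 - 1
  }, numeric(1))
  expect_lt(max(abs(rel_err)), 0.2)
})
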