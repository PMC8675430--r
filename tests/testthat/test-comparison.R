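test_that("fixed-effect pooling follows inverse-variance weights", {
  one <- fixed_effect_pool(2.5, 0.3)
  expect_equal(one$pooled, 2.5)
  expect_equal(one$pooled_se, 0.3)
  eq <- fixed_effect_pool(c(1, 2, 6), c(0.5, 0.5, 0.5))
  expect_equal(eq$pooled, 3)
  hand <- fixed_effect_pool(c(1, 3), c(1, 2))
  expect_equal(hand$pooled, 1.4)
  expect_equal(hand$pooled_se, 1 / sqrt(1.25))
  expect_equal(hand$pooled_se, 0.8944272, tolerance = 1e-6)
  expect_error(fixed_effect_pool(numeric(0), numeric(0)), "empty")
})

test_that("between-group heterogeneity matches hand-derived Q and p", {
  rows <- tibble::tibble(trait = c("t1", "t2"), group = c("A", "B"),
                         estimate = c(0, 3), se = c(1, 1))
  res <- between_group_heterogeneity(rows)
  expect_equal(res$Q_between, 4.5)
  expect_equal(res$p, pchisq(4.5, 1, lower.tail = FALSE))
  expect_equal(res$p, 0.0339, tolerance = 1e-2)
  # identical groups: exact null
  rows0 <- tibble::tibble(trait = c("t1", "t2"), group = c("A", "B"),
                          estimate = c(1, 1), se = c(0.5, 0.5))
  res0 <- between_group_heterogeneity(rows0)
  expect_equal(res0$Q_between, 0)
  expect_equal(res0$I2, 0)
  expect_equal(res0$p, 1)
})

test_that("heterogeneity equals the brute-force formula on random instances", {
  for (seed in 1:5) {
    rows <- withr::with_seed(seed, tibble::tibble(
      trait = paste0("t", 1:8),
      group = rep(c("A", "B"), each = 4),
      estimate = rnorm(8), se = runif(8, 0.2, 2)))
    res <- between_group_heterogeneity(rows)
    # naive evaluation, written independently of the implementation
    w <- 1 / rows$se^2
    th_all <- sum(w * rows$estimate) / sum(w)
    Q <- 0
    for (g in c("A", "B")) {
      i <- rows$group == g
      th_g <- sum(w[i] * rows$estimate[i]) / sum(w[i])
      Q <- Q + sum(w[i]) * (th_g - th_all)^2
    }
    expect_equal(res$Q_between, Q, tolerance = 1e-10)
    expect_equal(res$I2, max(0, (Q - 1) / Q), tolerance = 1e-10)
    expect_gte(res$Q_between, 0)
    expect_lt(res$I2, 1)
  }
})

test_that("heterogeneity agrees with metafor's fixed-effect subgroup model", {
  skip_if_not_installed("metafor")
  rows <- withr::with_seed(9, tibble::tibble(
    trait = paste0("t", 1:10),
    group = rep(c("A", "B"), each = 5),
    estimate = rnorm(10, rep(c(0, 1), each = 5)),
    se = runif(10, 0.3, 1)))
  res <- between_group_heterogeneity(rows)
  fe <- metafor::rma(yi = rows$estimate, sei = rows$se, method = "FE",
                     mods = ~ factor(rows$group))
  expect_equal(res$Q_between, unname(fe$QM), tolerance = 1e-8)
  expect_equal(res$p, unname(fe$QMp), tolerance = 1e-8)
})

test_that("row order does not matter and SE-less rows are excluded", {
  rows <- tibble::tibble(trait = paste0("t", 1:6),
                         group = rep(c("A", "B"), 3),
                         estimate = c(1, 2, 1.5, 2.5, 0.5, 3),
                         se = c(0.5, 1, 0.4, 0.8, 0.6, NA))
  res1 <- between_group_heterogeneity(rows)
  res2 <- between_group_heterogeneity(rows[sample(6), ] |>
                                        (\(d) d[order(d$trait), ])())
  expect_equal(res1$Q_between, res2$Q_between)
  expect_equal(res1$n_traits_used, 5)
  expect_equal(res1$n_excluded, 1)
  expect_match(res1$excluded_traits, "t6")
  bad <- rows[rows$group == "A", ]
  expect_error(between_group_heterogeneity(bad, groups = c("A", "B")), "B")
})

test_that("within-group I2 follows Cochran's Q", {
  est <- c(1, 2, 3); ses <- c(0.1, 0.1, 0.1)
  res <- within_group_heterogeneity(est, ses)
  w <- 1 / ses^2
  pool <- sum(w * est) / sum(w)
  Q <- sum(w * (est - pool)^2)
  expect_equal(res$Q, Q)
  expect_equal(res$I2, (Q - 2) / Q)
})

test_that("BH adjustment matches the naive step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m))
      adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    adj
  }
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(12)^2)
    adj <- bh_fdr(p)
    expect_equal(adj, naive_bh(p), tolerance = 1e-12)
    # adjustment preserves the ordering of the raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation test matches hand computation", {
  expect_equal(pearson_corr_test(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_corr_test(1:5, -(1:5))$r, -1)
  res <- pearson_corr_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(tstat, 3, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$p, 0.104, tolerance = 1e-2)
  expect_error(pearson_corr_test(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Fisher's exact test uses point-probability two-sidedness", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 0.0079,
               tolerance = 1e-2)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 4, 0), 2)), 1)  # zero margin
  # enumeration oracle: sum hypergeometric probabilities <= observed
  tab <- matrix(c(7, 2, 3, 8), 2)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- max(0, k - n2):min(k, m)
  pr <- dhyper(x, m, n2, k)
  p_oracle <- sum(pr[pr <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(tab), p_oracle, tolerance = 1e-10)
})

test_that("Welch's t test matches the textbook formula", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  x <- c(10, 12, 14); y <- c(20, 24, 28)
  res <- welch_t_test(x, y)
  sx2 <- var(x) / 3; sy2 <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df_hand <- (sx2 + sy2)^2 / (sx2^2 / 2 + sy2^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # |t| grows with the shift between equal-variance samples
  t1 <- abs(welch_t_test(c(1, 2, 3), c(2, 3, 4))$t)
  t2 <- abs(welch_t_test(c(1, 2, 3), c(4, 5, 6))$t)
  expect_gt(t2, t1)
})

test_that("compare_groups applies FDR across the configured family only", {
  metrics <- withr::with_seed(21, tibble::tibble(
    trait = paste0("t", 1:12),
    group = rep(c("A", "B", "C"), each = 4),
    estimate = c(rnorm(4, 0), rnorm(4, 3), rnorm(4, 0.2)),
    se = runif(12, 0.3, 0.6)))
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  res <- compare_groups(metrics, pairs)
  expect_equal(nrow(res), 3)
  expect_equal(res$fdr, bh_fdr(res$p))
  expect_true(all(res$fdr >= res$p - 1e-15))
})

test_that("forest data carries per-trait intervals plus pooled diamonds", {
  metrics <- tibble::tibble(trait = c("t1", "t2", "t3"),
                            group = c("A", "A", "B"),
                            estimate = c(1, 2, 3), se = c(0.1, 0.2, 0.1))
  fd <- forest_data(metrics)
  expect_equal(sum(fd$is_pooled), 2)
  expect_equal(nrow(fd), 5)
  t1 <- fd[fd$label == "t1", ]
  expect_equal(t1$lo, 1 - 1.96 * 0.1)
})
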