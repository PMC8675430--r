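#' True generative parameters for synthetic GWAS summary statistics
#'
#' Mirrors [mixture_params()] on the generative side and adds the study
#' design: SNP count `M`, sample size (scalar or per-SNP vector), and for
#' case-control designs the case/control counts from which the effective
#' sample size is derived.
#'
#' @param kind `"M2"` or `"M3"`.
#' @param pi_c sSNP proportion.
#' @param sigma2 M2 effect-size variance.
#' @param sigma2_1,sigma2_2,prop M3 component variances and cluster-1
#'   fraction.
#' @param intercept_a Null z-score variance (1 = no stratification).
#' @param M Number of SNPs to simulate.
#' @param n Sample size, scalar or length-`M` vector (quantitative design).
#' @param design `"quantitative"` or `"case_control"`.
#' @param n_cases,n_controls Case-control counts; `n` is then the implied
#'   effective sample size.
#' @return A list of class `truth_params` with a `params` field holding the
#'   corresponding [mixture_params()].
#' @export
truth_params <- function(kind = c("M2", "M3"), pi_c, sigma2 = NULL,
                         sigma2_1 = NULL, sigma2_2 = NULL, prop = NULL,
                         intercept_a = 1, M, n = NULL,
                         design = c("quantitative", "case_control"),
                         n_cases = NULL, n_controls = NULL) {
  kind <- match.arg(kind)
  design <- match.arg(design)
  params <- mixture_params(kind, pi_c = pi_c, sigma2 = sigma2,
                           sigma2_1 = sigma2_1, sigma2_2 = sigma2_2,
                           prop = prop, intercept_a = intercept_a)
  stopifnot(M >= 1)
  if (design == "case_control") {
    if (is.null(n_cases) || is.null(n_controls))
      stop("case_control design requires n_cases and n_controls")
    n <- effective_sample_size(n_cases, n_controls)
  }
  if (is.null(n)) stop("sample size n is required")
  stopifnot(all(n > 0), length(n) %in% c(1L, M))
  structure(list(params = params, M = as.integer(M), n = n,
                 design = design, n_cases = n_cases,
                 n_controls = n_controls),
            class = "truth_params")
}

#' Configuration of the synthetic-data generator
#'
#' @param seed Integer seed; every draw in the generator flows from it.
#' @param maf_range MAF sampled uniformly on this interval
#'   (default `c(0.05, 0.5)`).
#' @param n_mhc_snps SNPs placed inside the MHC interval (chr6:26-34 Mb).
#' @param n_z_outliers SNPs overwritten with `z^2 > 80`.
#' @param n_low_n_snps SNPs overwritten with `n_eff = low_n_value`.
#' @param low_n_value Effective sample size given to low-N artifact SNPs
#'   (default 1% of the study size at injection time).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, maf_range = c(0.05, 0.5),
                       n_mhc_snps = 0, n_z_outliers = 0, n_low_n_snps = 0,
                       low_n_value = NULL) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            n_mhc_snps >= 0, n_z_outliers >= 0, n_low_n_snps >= 0)
  structure(list(seed = as.integer(seed), maf_range = maf_range,
                 n_mhc_snps = as.integer(n_mhc_snps),
                 n_z_outliers = as.integer(n_z_outliers),
                 n_low_n_snps = as.integer(n_low_n_snps),
                 low_n_value = low_n_value),
            class = "sim_config")
}

#' Simulate GWAS summary statistics with known truth
#'
#' Per SNP: a component label is drawn (null with probability `1 - pi_c`,
#' otherwise cluster 1 with probability `prop` for M3), a true effect
#' `beta` from the component's normal (0 for null SNPs), and a z-score
#' `z = sqrt(n) * beta + e` with `e ~ N(0, intercept_a)`. The reported
#' `se` is `1 / sqrt(n)`, so the reported `beta` column (`z * se`) sits on
#' the standardized scale, and `p` is the two-sided normal tail. Positions
#' are uniform over 22 synthetic 100-Mb chromosomes, except
#' `config$n_mhc_snps` SNPs placed inside chr6:26-34 Mb. The generator is
#' deterministic given `config$seed`.
#'
#' @param truth A [truth_params()].
#' @param config A [sim_config()].
#' @return A list: `table` (canonical summary-statistics tibble with a
#'   `study_meta` attribute), `labels` (tibble `snp_id`, `component` — 0 =
#'   null, 1/2 = sSNP cluster — and `beta_true`), `panel` (a matching
#'   [reference_panel()] over all simulated SNPs), `truth`, and
#'   `realized_h2` (the realized `sum(beta_true^2)`).
#' @export
simulate_sumstats <- function(truth, config = sim_config()) {
  stopifnot(inherits(truth, "truth_params"), inherits(config, "sim_config"))
  M <- truth$M
  p <- truth$params
  n <- rep_len(truth$n, M)
  withr::with_seed(config$seed, {
    if (p$kind == "M2") {
      comp <- ifelse(runif(M) < p$pi_c, 1L, 0L)
      sds <- c(0, sqrt(p$sigma2))
    } else {
      u <- runif(M)
      comp <- ifelse(u >= p$pi_c, 0L,
                     ifelse(runif(M) < p$prop, 1L, 2L))
      sds <- c(0, sqrt(p$sigma2_1), sqrt(p$sigma2_2))
    }
    beta_true <- rnorm(M, 0, sds[comp + 1L])
    z <- sqrt(n) * beta_true + rnorm(M, 0, sqrt(p$intercept_a))
    maf <- runif(M, config$maf_range[1], config$maf_range[2])
    chrom <- as.character(sample.int(22L, M, replace = TRUE))
    pos <- as.integer(floor(runif(M, 1, 1e8)))
    if (config$n_mhc_snps > 0) {
      idx <- sample.int(M, config$n_mhc_snps)
      chrom[idx] <- "6"
      pos[idx] <- as.integer(floor(runif(config$n_mhc_snps, 26e6, 34e6 + 1)))
    }
  })
  se <- 1 / sqrt(n)
  tab <- tibble::tibble(
    snp_id = paste0("rs", seq_len(M)),
    chrom = chrom, pos = pos,
    a1 = "A", a2 = "G", maf = maf,
    beta = z * se, se = se, z = z, n_eff = n,
    p = two_sided_p(z))
  meta <- study_meta("synthetic", design = truth$design,
                     n_total = if (truth$design == "quantitative")
                       max(n) else NULL,
                     n_cases = truth$n_cases, n_controls = truth$n_controls)
  attr(tab, "meta") <- meta
  panel <- reference_panel(tab[, c("snp_id", "chrom", "pos", "maf")], M = M)
  list(table = tab,
       labels = tibble::tibble(snp_id = tab$snp_id, component = comp,
                               beta_true = beta_true),
       panel = panel, truth = truth,
       realized_h2 = sum(beta_true^2))
}

#' Inject QC-violating artifacts into a clean table
#'
#' Overwrites seeded, randomly chosen rows to create exactly
#' `n_z_outliers` rows with `z^2 > 80` (z set to +/-10), `n_low_n_snps`
#' rows with `n_eff = low_n_value` (default 1% of the median study size),
#' and `n_mhc_snps` rows relocated into the MHC interval. Overlapping
#' assignments are resolved by priority z-outlier > low-N > MHC, so the
#' manifest's final counts are exact.
#'
#' @param table Canonical summary-statistics tibble.
#' @param config A [sim_config()] carrying the artifact counts and seed.
#' @return A list: `table` (modified copy) and `manifest` (tibble `snp_id`,
#'   `artifact`).
#' @export
inject_artifacts <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  tab <- tibble::as_tibble(table)
  total <- config$n_z_outliers + config$n_low_n_snps + config$n_mhc_snps
  if (total > nrow(tab)) stop("artifact counts exceed table rows")
  if (total == 0)
    return(list(table = tab, manifest = tibble::tibble(
      snp_id = character(0), artifact = character(0))))
  low_n_value <- config$low_n_value %||% (0.01 * median(tab$n_eff))
  withr::with_seed(config$seed + 1L, {
    rows <- sample.int(nrow(tab), total)
    signs <- sample(c(-1, 1), config$n_z_outliers, replace = TRUE)
    mhc_pos <- as.integer(floor(runif(config$n_mhc_snps, 26e6, 34e6 + 1)))
  })
  i_z <- rows[seq_len(config$n_z_outliers)]
  i_low <- rows[config$n_z_outliers + seq_len(config$n_low_n_snps)]
  i_mhc <- rows[config$n_z_outliers + config$n_low_n_snps +
                  seq_len(config$n_mhc_snps)]
  if (length(i_z)) {
    tab$z[i_z] <- 10 * signs
    tab$beta[i_z] <- tab$z[i_z] * tab$se[i_z]
    tab$p[i_z] <- two_sided_p(tab$z[i_z])
  }
  if (length(i_low)) tab$n_eff[i_low] <- low_n_value
  if (length(i_mhc)) {
    tab$chrom[i_mhc] <- "6"
    tab$pos[i_mhc] <- mhc_pos
  }
  manifest <- tibble::tibble(
    snp_id = tab$snp_id[c(i_z, i_low, i_mhc)],
    artifact = rep(c("z_outlier", "low_n", "mhc"),
                   c(length(i_z), length(i_low), length(i_mhc))))
  list(table = tab, manifest = manifest)
}

#' Simulate a roster of traits in labelled groups
#'
#' Generates one synthetic GWAS per trait from a per-group template whose
#' variance parameters are jittered multiplicatively (log-normal with the
#' given coefficient of variation on the log scale), producing a
#' ready-to-run multi-trait fixture with known between-group differences.
#'
#' @param group_specs List of group specifications, each a list with
#'   `group` (label), `k` (number of traits), `template` (a
#'   [truth_params()]), and optional `jitter_sd` (SD of the log-normal
#'   multiplier applied to the variance parameters; default 0 = none).
#' @param config A [sim_config()]; trait seeds are derived from
#'   `config$seed`.
#' @return A list of per-trait entries: `meta` ([study_meta()]), `table`,
#'   `panel`, `truth`, `labels`, `realized_h2`.
#' @export
simulate_trait_panel <- function(group_specs, config = sim_config()) {
  stopifnot(length(group_specs) >= 1)
  out <- list()
  trait_i <- 0L
  for (gs in group_specs) {
    stopifnot(!is.null(gs$group), !is.null(gs$k), gs$k >= 1,
              inherits(gs$template, "truth_params"))
    jitter_sd <- gs$jitter_sd %||% 0
    for (j in seq_len(gs$k)) {
      trait_i <- trait_i + 1L
      seed_t <- config$seed + 1000L * trait_i
      tmpl <- gs$template
      p <- tmpl$params
      if (jitter_sd > 0) {
        mult <- withr::with_seed(seed_t - 1L, exp(rnorm(3, 0, jitter_sd)))
        if (p$kind == "M2") {
          p <- mixture_params("M2", pi_c = p$pi_c, sigma2 = p$sigma2 * mult[1],
                              intercept_a = p$intercept_a)
        } else {
          s1 <- p$sigma2_1 * mult[1]; s2 <- p$sigma2_2 * mult[2]
          p <- mixture_params("M3", pi_c = p$pi_c,
                              sigma2_1 = max(s1, s2), sigma2_2 = min(s1, s2),
                              prop = p$prop, intercept_a = p$intercept_a)
        }
      }
      tr <- structure(list(params = p, M = tmpl$M, n = tmpl$n,
                           design = tmpl$design, n_cases = tmpl$n_cases,
                           n_controls = tmpl$n_controls),
                      class = "truth_params")
      cfg_t <- config
      cfg_t$seed <- seed_t
      sim <- simulate_sumstats(tr, cfg_t)
      meta <- study_meta(paste0(gs$group, "_", j), group_label = gs$group,
                        design = tmpl$design,
                        n_total = if (tmpl$design == "quantitative")
                          max(rep_len(tmpl$n, 1)) else NULL,
                        n_cases = tmpl$n_cases, n_controls = tmpl$n_controls)
      attr(sim$table, "meta") <- meta
      out[[meta$trait_name]] <- list(meta = meta, table = sim$table,
                                     panel = sim$panel, truth = tr,
                                     labels = sim$labels,
                                     realized_h2 = sim$realized_h2)
    }
  }
  out
}

#' Write the truth record of a simulation as JSON and TSV
#'
#' @param sim Result of [simulate_sumstats()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sumstats_path <- file.path(dir, paste0(prefix, "_sumstats.tsv"))
  labels_path <- file.path(dir, paste0(prefix, "_truth_labels.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_sumstats(sim$table, sumstats_path)
  readr::write_tsv(sim$labels, labels_path)
  p <- sim$truth$params
  jsonlite::write_json(list(
    kind = p$kind, pi_c = p$pi_c, sigma2 = p$sigma2,
    sigma2_1 = p$sigma2_1, sigma2_2 = p$sigma2_2, prop = p$prop,
    intercept_a = p$intercept_a, M = sim$truth$M,
    design = sim$truth$design, realized_h2 = sim$realized_h2),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(sumstats_path, labels_path, truth_path))
}
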