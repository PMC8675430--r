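#' Run configuration for the full architecture pipeline
#'
#' @param traits Either the output of [simulate_trait_panel()] (in-memory
#'   tables) or a list of entries with `path`, `column_map` and `meta` to
#'   be read with [read_sumstats()].
#' @param panel A [reference_panel()], or `NULL` to build one per trait
#'   from its own simulated panel (in-memory rosters carry their panels).
#' @param qc A [qc_config()].
#' @param fit_settings List: `intercept` ("estimate"/"fixed"), `method`
#'   ("direct"/"em"), `tol`, `max_iter`.
#' @param comparison_pairs List of length-2 character vectors of group
#'   labels; BH-FDR is applied across exactly this family, separately for
#'   each compared metric.
#' @param projection List: `grid_start`, `grid_end`, `step`, `threshold`,
#'   `alpha`; set to `NULL` to skip projections.
#' @param qq List: `n_draws`, `band`; `NULL` skips QQ data.
#' @param seed Master seed; per-trait seeds are derived from it.
#' @param outdir Optional directory; when set, all result tables are
#'   written there as TSV/JSON.
#' @return A list of class `run_config`.
#' @export
run_config <- function(traits, panel = NULL, qc = qc_config(),
                       fit_settings = list(),
                       comparison_pairs = list(),
                       projection = list(),
                       qq = NULL,
                       seed = 1, outdir = NULL) {
  fit_settings <- modifyList(list(intercept = "estimate", method = "direct",
                                  tol = 1e-8, max_iter = 2000), fit_settings)
  if (!is.null(projection))
    projection <- modifyList(list(grid_start = 5e4, grid_end = 2e8,
                                  step = 5e4, threshold = 99, alpha = 5e-8),
                             projection)
  nm <- names(traits) %||% vapply(traits, function(t)
    (t$meta %||% list(trait_name = NA_character_))$trait_name, character(1))
  if (anyDuplicated(nm)) stop("trait names must be unique")
  groups <- vapply(traits, function(t) t$meta$group_label, character(1))
  for (pr in comparison_pairs)
    if (!all(pr %in% groups))
      stop("comparison pair references undeclared group: ",
           paste(setdiff(pr, groups), collapse = ", "))
  structure(list(traits = traits, panel = panel, qc = qc,
                 fit_settings = fit_settings,
                 comparison_pairs = comparison_pairs,
                 projection = projection, qq = qq,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Thin front end over [run_config()] for file-based rosters: the YAML
#' lists per-trait paths, column maps and study metadata, the panel path,
#' and any setting overrides.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package")
  y <- yaml::read_yaml(path)
  traits <- lapply(y$traits, function(t) {
    meta <- do.call(study_meta, t$meta)
    tab <- read_sumstats(t$path, t$column_map, meta)
    list(meta = meta, table = tab)
  })
  names(traits) <- vapply(traits, function(t) t$meta$trait_name, character(1))
  panel <- if (!is.null(y$reference_panel))
    read_reference_panel(y$reference_panel, M = y$M) else NULL
  run_config(traits, panel = panel,
             qc = do.call(qc_config, y$qc %||% list()),
             fit_settings = y$fit_settings %||% list(),
             comparison_pairs = y$comparison_pairs %||% list(),
             projection = y$projection %||% list(),
             qq = y$qq,
             seed = y$seed %||% 1, outdir = y$outdir)
}

#' Run the full genetic-architecture pipeline over a trait roster
#'
#' For each trait: QC against the panel, fit of both mixture models (M3
#' initialized from M2), model selection, architecture metrics, and
#' optionally projection curves and QQ data. Per-trait failures are
#' isolated: the trait is recorded with a failure status and excluded from
#' downstream comparisons (as is any trait whose standard errors could not
#' be estimated), never aborting the run. Group comparisons (polygenicity,
#' discoverability and heritability heterogeneity with BH-FDR across the
#' configured pairs) and covariate correlations run on the surviving rows.
#' The run is deterministic given the config.
#'
#' @param config A [run_config()].
#' @return A list of class `result_bundle`: `fits` (per trait: `m2`, `m3`,
#'   `selected`), `qc_reports`, `metrics` (tidy per-trait table with
#'   `status`), `projection` and `projection_summary`, `comparisons`,
#'   `correlations`, `forest` (per-trait intervals plus pooled diamonds,
#'   per metric), `qq`, `log` (tibble of per-stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fs <- config$fit_settings
  log <- list()
  note <- function(trait, stage, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(
      trait = trait, stage = stage, message = msg)
  }

  fits <- list(); qc_reports <- list(); qq <- list()
  metric_rows <- list(); proj_rows <- list(); proj_summary <- list()

  for (nm in names(config$traits)) {
    tr <- config$traits[[nm]]
    meta <- tr$meta
    status <- "ok"
    row <- NULL
    res <- tryCatch({
      panel <- config$panel %||% tr$panel
      if (is.null(panel)) stop("no reference panel for trait ", nm)
      qcres <- qc_filter(tr$table, panel, config$qc)
      qc_reports[[nm]] <- qcres$report
      note(nm, "qc", sprintf("%d -> %d SNPs", qcres$report$n_input,
                             qcres$report$n_output))
      m2 <- fit_mixture(qcres$table, "M2", intercept = fs$intercept,
                        method = fs$method, tol = fs$tol,
                        max_iter = fs$max_iter)
      m3 <- fit_mixture(qcres$table, "M3", m2_fit = m2,
                        intercept = fs$intercept, method = fs$method,
                        tol = fs$tol, max_iter = fs$max_iter)
      sel <- select_model(m2, m3)
      best <- if (sel == "M2") m2 else m3
      note(nm, "fit", sprintf("selected %s (loglik %.1f)", sel, best$loglik))
      fits[[nm]] <- list(m2 = m2, m3 = m3, selected = sel)
      if (!best$converged) status <- "fit-failed"
      else if (!best$se_available) status <- "se-unavailable"
      row <- architecture_metrics(best, trait = nm, group = meta$group_label)
      if (!is.null(config$projection) && best$converged) {
        pj <- config$projection
        curve <- required_n(best, grid_start = pj$grid_start,
                            grid_end = pj$grid_end, step = pj$step,
                            threshold = pj$threshold, alpha = pj$alpha)
        proj_rows[[nm]] <- projection_table(curve, trait = nm)
        proj_summary[[nm]] <- tibble::tibble(
          trait = nm, n_required = curve$n_required,
          censored = curve$censored, gv_at_max = curve$gv_at_max)
      }
      if (!is.null(config$qq) && best$converged) {
        qq[[nm]] <- qq_expected(best, qcres$table,
                                n_draws = config$qq$n_draws %||% 200,
                                seed = config$seed + match(nm, names(config$traits)),
                                band = config$qq$band %||% 0.80)
      }
      TRUE
    }, error = function(e) {
      note(nm, "error", conditionMessage(e))
      FALSE
    })
    if (!res) {
      status <- "fit-failed"
      row <- architecture_metrics_failed(nm, meta$group_label)
    }
    row$status <- status
    if (status != "ok")
      note(nm, "exclusion",
           paste("excluded from comparisons:", status))
    # covariates travel with the row for correlation screens
    for (cv in names(meta$covariates))
      row[[paste0("cov_", cv)]] <- meta$covariates[[cv]]
    row$n_eff_mean <- mean(tr$table$n_eff)
    metric_rows[[nm]] <- row
  }
  metrics <- dplyr::bind_rows(metric_rows)

  comparisons <- NULL
  if (length(config$comparison_pairs)) {
    usable <- metrics[metrics$status == "ok", , drop = FALSE]
    comp_list <- list()
    for (metric_name in c("polygenicity", "discoverability", "heritability")) {
      cols <- switch(metric_name,
                     polygenicity = c("n_ssnp", "se_pi"),
                     discoverability = c("median_abs_effect", "mae_se"),
                     heritability = c("h2", "se_h2"))
      rows <- tibble::tibble(trait = usable$trait, group = usable$group,
                             estimate = usable[[cols[1]]],
                             se = usable[[cols[2]]])
      if (metric_name == "polygenicity" && nrow(rows))
        rows$se <- rows$se * metrics_M(config)  # pi_c SE -> sSNP-count SE
      cmp <- tryCatch(
        compare_groups(rows, config$comparison_pairs),
        error = function(e) { note(NA_character_, "comparison",
                                   conditionMessage(e)); NULL })
      if (!is.null(cmp)) { cmp$metric <- metric_name; comp_list[[metric_name]] <- cmp }
    }
    comparisons <- dplyr::bind_rows(comp_list)
  }

  correlations <- pipeline_correlations(metrics)

  # per-trait intervals plus pooled diamonds, one block per metric
  usable_all <- metrics[metrics$status == "ok", , drop = FALSE]
  forest <- if (nrow(usable_all)) dplyr::bind_rows(
    lapply(c("polygenicity", "discoverability", "heritability"), function(mn) {
      cols <- switch(mn,
                     polygenicity = c("n_ssnp", "se_pi"),
                     discoverability = c("median_abs_effect", "mae_se"),
                     heritability = c("h2", "se_h2"))
      se <- usable_all[[cols[2]]]
      if (mn == "polygenicity") se <- se * metrics_M(config)
      fd <- forest_data(tibble::tibble(trait = usable_all$trait,
                                       group = usable_all$group,
                                       estimate = usable_all[[cols[1]]],
                                       se = se))
      fd$metric <- mn
      fd
    })) else NULL

  bundle <- structure(list(
    fits = fits, qc_reports = qc_reports, metrics = metrics,
    projection = dplyr::bind_rows(proj_rows),
    projection_summary = dplyr::bind_rows(proj_summary),
    comparisons = comparisons, correlations = correlations,
    forest = forest,
    qq = qq, log = dplyr::bind_rows(log), seed = config$seed),
    class = "result_bundle")

  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

# placeholder row for a trait whose fit failed outright
architecture_metrics_failed <- function(trait, group) {
  tibble::tibble(trait = trait, group = group, model = NA_character_,
                 pi_c = NA_real_, se_pi = NA_real_, n_ssnp = NA_real_,
                 n_ssnp_lo = NA_real_, n_ssnp_hi = NA_real_,
                 n_ssnp_cluster1 = NA_real_, median_abs_effect = NA_real_,
                 mae_lo = NA_real_, mae_hi = NA_real_, mae_se = NA_real_,
                 clamp_flags = "", h2 = NA_real_, se_h2 = NA_real_,
                 se_available = FALSE, converged = FALSE)
}

metrics_M <- function(config) {
  if (!is.null(config$panel)) return(config$panel$M)
  Ms <- vapply(config$traits, function(t)
    if (!is.null(t$panel)) t$panel$M else NA_real_, numeric(1))
  if (all(is.na(Ms))) 1 else stats::median(Ms, na.rm = TRUE)
}

# Pearson screens of architecture metrics against any cov_* columns
pipeline_correlations <- function(metrics) {
  cov_cols <- grep("^cov_", names(metrics), value = TRUE)
  targets <- c(polygenicity = "n_ssnp", discoverability = "median_abs_effect",
               heritability = "h2")
  out <- list()
  for (cv in cov_cols) for (tg in names(targets)) {
    x <- metrics[[cv]]; y <- metrics[[targets[tg]]]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) >= 3 && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0) {
      ct <- pearson_corr_test(x[keep], y[keep])
      out[[length(out) + 1]] <- tibble::tibble(
        covariate = sub("^cov_", "", cv), metric = tg,
        r = ct$r, p = ct$p, n = ct$n)
    }
  }
  # intrinsic screen: polygenicity vs discoverability across traits
  keep <- stats::complete.cases(metrics$n_ssnp, metrics$median_abs_effect)
  if (sum(keep) >= 3 && stats::sd(metrics$n_ssnp[keep]) > 0 &&
      stats::sd(metrics$median_abs_effect[keep]) > 0) {
    ct <- pearson_corr_test(metrics$n_ssnp[keep],
                            metrics$median_abs_effect[keep])
    out[[length(out) + 1]] <- tibble::tibble(
      covariate = "n_ssnp", metric = "discoverability",
      r = ct$r, p = ct$p, n = ct$n)
  }
  dplyr::bind_rows(out)
}

#' Write a result bundle's tables to a directory
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$metrics, file.path(dir, "metrics.tsv"))
  if (!is.null(bundle$comparisons) && nrow(bundle$comparisons))
    readr::write_tsv(bundle$comparisons, file.path(dir, "comparisons.tsv"))
  if (nrow(bundle$projection))
    readr::write_tsv(bundle$projection, file.path(dir, "projection.tsv"))
  if (nrow(bundle$projection_summary))
    readr::write_tsv(bundle$projection_summary,
                     file.path(dir, "projection_summary.tsv"))
  if (!is.null(bundle$correlations) && nrow(bundle$correlations))
    readr::write_tsv(bundle$correlations, file.path(dir, "correlations.tsv"))
  if (!is.null(bundle$forest) && nrow(bundle$forest))
    readr::write_tsv(bundle$forest, file.path(dir, "forest.tsv"))
  readr::write_tsv(bundle$log, file.path(dir, "run_log.tsv"))
  for (nm in names(bundle$fits)) {
    write_fit_json(bundle$fits[[nm]][[tolower(bundle$fits[[nm]]$selected)]],
                   file.path(dir, paste0("fit_", nm, ".json")))
  }
  for (nm in names(bundle$qq)) {
    q <- bundle$qq[[nm]]
    readr::write_tsv(tibble::tibble(
      observed_neglog10p = q$observed_neglog10p,
      expected_neglog10p = q$expected_neglog10p,
      band_lo = q$band_lo, band_hi = q$band_hi),
      file.path(dir, paste0("qq_", nm, ".tsv")))
  }
  invisible(dir)
}

#' Emulate smaller studies of the same trait
#'
#' For each fraction `f`, scales every SNP's effective sample size by `f`
#' and rescales its z-score as `z * sqrt(f)` (true effects held fixed),
#' then tops the sampling noise back up to unit variance with a seeded
#' `N(0, 1 - f)` draw — the signal part of the rescaled score is
#' `sqrt(f * n) * beta` but its noise variance is only `f`, whereas a real
#' study of `f * n` participants has unit-variance noise. The result has
#' the marginal law a study of `f` times the size would produce; used to
#' check how discoverability estimates respond to sample size (the
#' winner's-curse sensitivity analysis).
#'
#' @param table Canonical summary-statistics tibble.
#' @param fractions Fractions in (0, 1].
#' @param seed Integer seed for the noise top-up (`f = 1` adds none and is
#'   an exact identity).
#' @return A named list of tables, one per fraction.
#' @export
subsample_study <- function(table, fractions, seed = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  out <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    tab <- tibble::as_tibble(table)
    tab$n_eff <- tab$n_eff * f
    tab$z <- tab$z * sqrt(f)
    if (f < 1) {
      tab$z <- tab$z + withr::with_seed(seed + i,
                                        rnorm(nrow(tab), 0, sqrt(1 - f)))
    }
    tab$se <- 1 / sqrt(tab$n_eff)
    tab$beta <- tab$z * tab$se
    tab$p <- two_sided_p(tab$z)
    for (at in c("M_reference", "meta"))
      attr(tab, at) <- attr(table, at, exact = TRUE)
    tab
  })
  names(out) <- paste0("f", fractions)
  out
}
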