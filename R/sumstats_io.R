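#' Quality-control configuration for GWAS summary statistics
#'
#' Thresholds for the four sequential filters applied by [qc_filter()]:
#' restriction to the reference panel at a minimum minor allele frequency,
#' removal of the major histocompatibility complex (MHC) region, removal of
#' SNPs with extreme association statistics (z-squared above `z2_max`), and
#' removal of SNPs with low effective sample size relative to the study's
#' upper quantile.
#'
#' @param low_n_fraction Fraction of the reference quantile of `n_eff` below
#'   which a SNP is dropped (default 0.67).
#' @param low_n_quantile Quantile of `n_eff` (computed on SNPs surviving the
#'   preceding filters) used as the reference sample size (default 0.90).
#' @param z2_max SNPs with `z^2` strictly greater than this are removed
#'   (default 80); the boundary value is retained.
#' @param maf_min Minimum panel minor allele frequency (default 0.05).
#' @param mhc_chrom,mhc_start,mhc_end MHC interval (1-based, inclusive);
#'   defaults chr6:26,000,000-34,000,000.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(low_n_fraction = 0.67, low_n_quantile = 0.90,
                      z2_max = 80, maf_min = 0.05,
                      mhc_chrom = "6", mhc_start = 26e6, mhc_end = 34e6) {
  stopifnot(low_n_fraction > 0, is_fraction(low_n_quantile),
            z2_max > 0, maf_min > 0, mhc_start < mhc_end)
  structure(list(low_n_fraction = low_n_fraction,
                 low_n_quantile = low_n_quantile,
                 z2_max = z2_max, maf_min = maf_min,
                 mhc_chrom = as.character(mhc_chrom),
                 mhc_start = mhc_start, mhc_end = mhc_end),
            class = "qc_config")
}

#' Study-level metadata for one GWAS
#'
#' @param trait_name Trait label, unique within a roster.
#' @param group_label Trait-group label used in between-group comparisons
#'   (e.g. "cortical surface area", "neuropsychiatric").
#' @param design `"quantitative"` or `"case_control"`.
#' @param n_total Total number of enrolled participants; used as the per-SNP
#'   effective sample size when the summary statistics carry no N column.
#' @param n_cases,n_controls Required for case-control designs; the
#'   effective sample size is then `4 / (1/n_cases + 1/n_controls)`.
#' @param covariates Optional named list of per-trait scalars (e.g. LDSC
#'   intercept, test-retest correlation) carried through to comparisons.
#' @return A list of class `study_meta` with an `n_eff` field resolved from
#'   the design.
#' @export
study_meta <- function(trait_name, group_label = "ungrouped",
                       design = c("quantitative", "case_control"),
                       n_total = NULL, n_cases = NULL, n_controls = NULL,
                       covariates = list()) {
  design <- match.arg(design)
  if (design == "case_control") {
    if (is.null(n_cases) || is.null(n_controls))
      stop("case_control design requires n_cases and n_controls")
    n_eff <- effective_sample_size(n_cases, n_controls)
    n_total <- n_total %||% (n_cases + n_controls)
  } else {
    n_eff <- n_total
  }
  structure(list(trait_name = trait_name, group_label = group_label,
                 design = design, n_total = n_total,
                 n_cases = n_cases, n_controls = n_controls,
                 n_eff = n_eff, covariates = covariates),
            class = "study_meta")
}

#' Effective sample size of a case-control GWAS
#'
#' The harmonic-mean form `4 / (1/n_cases + 1/n_controls)`, which equals the
#' total sample size for a balanced design and is smaller otherwise.
#'
#' @param n_cases,n_controls Positive case and control counts.
#' @return The effective sample size (scalar or vector).
#' @export
#' @examples
#' effective_sample_size(1000, 1000) # 2000
#' effective_sample_size(100, 300)   # 300
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("n_cases and n_controls must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Reference SNP panel
#'
#' @param entries Data frame with columns `snp_id`, `chrom`, `pos`, `maf`;
#'   `snp_id` must be unique.
#' @param M Number of reference SNPs used as the polygenicity denominator;
#'   defaults to `nrow(entries)`, but may be set larger when `entries` is a
#'   subset of the panel the denominator refers to.
#' @return A list of class `reference_panel` with fields `entries` and `M`.
#' @export
reference_panel <- function(entries, M = nrow(entries)) {
  entries <- tibble::as_tibble(entries)
  req <- c("snp_id", "chrom", "pos", "maf")
  if (!all(req %in% names(entries)))
    stop("panel must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(entries$snp_id))
    stop("panel snp_id values must be unique")
  stopifnot(M >= nrow(entries))
  entries$chrom <- as.character(entries$chrom)
  structure(list(entries = entries, M = as.numeric(M)),
            class = "reference_panel")
}

#' Read a reference panel from a delimited file
#'
#' @param path TSV/CSV file with columns `snp_id`, `chrom`, `pos`, `maf`.
#' @param M Polygenicity denominator; defaults to the number of rows read.
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path, M = NULL) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  reference_panel(tab, M = M %||% nrow(tab))
}

# first non-header line decides between tab, comma and whitespace
guess_delim <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else " "
}

canonical_cols <- c("snp_id", "chrom", "pos", "a1", "a2", "maf",
                    "beta", "se", "z", "n_eff", "p")

#' Read GWAS summary statistics into the canonical table
#'
#' Reads a headered delimited file (tab, comma or whitespace separated; gzip
#' transparently supported), renames columns through `column_map`, computes
#' the z-score as `beta / se` when no z column is mapped, and fills per-SNP
#' effective sample sizes from `meta` when the file carries no N column.
#' Duplicated SNP ids keep their first occurrence; dropped duplicates and
#' unparseable numeric rows are counted in the `parse_warnings` attribute.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector or list mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `maf`, `beta`, `se`, `z`,
#'   `n_eff`, `p`) to column names in the file. `snp_id` plus either
#'   (`beta`, `se`) or `z` are mandatory.
#' @param meta A [study_meta()] object supplying the trait label, group and
#'   the study-wide effective sample size.
#' @return A tibble with the canonical columns; attributes `meta` and
#'   `parse_warnings` (named counts).
#' @export
read_sumstats <- function(path, column_map, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(meta, "study_meta"))
  column_map <- unlist(column_map)
  if (!"snp_id" %in% names(column_map))
    stop("column_map is missing mandatory column: snp_id")
  if (!("z" %in% names(column_map)) &&
      !all(c("beta", "se") %in% names(column_map)))
    stop("column_map is missing mandatory column: z (or beta and se)")

  raw <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols))
    stop("column not present in file: ", paste(missing_cols, collapse = ", "))

  tab <- tibble::tibble(snp_id = raw[[column_map[["snp_id"]]]])
  for (cc in setdiff(canonical_cols, "snp_id")) {
    tab[[cc]] <- if (cc %in% names(column_map))
      raw[[column_map[[cc]]]] else NA_character_
  }
  num_cols <- setdiff(canonical_cols, c("snp_id", "chrom", "a1", "a2"))
  mapped_num <- intersect(num_cols, names(column_map))
  for (cc in num_cols) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))

  # rows where a mapped numeric field failed to parse are skipped, not kept NA
  bad <- rep(FALSE, nrow(tab))
  for (cc in mapped_num) bad <- bad | is.na(tab[[cc]])
  n_bad <- sum(bad)
  tab <- tab[!bad, , drop = FALSE]

  dup <- duplicated(tab$snp_id)
  n_dup <- sum(dup)
  tab <- tab[!dup, , drop = FALSE]

  if (!"z" %in% names(column_map)) {
    if (any(tab$se <= 0)) {
      drop <- tab$se <= 0
      n_bad <- n_bad + sum(drop)
      tab <- tab[!drop, , drop = FALSE]
    }
    tab$z <- tab$beta / tab$se
  }
  if (!"n_eff" %in% names(column_map)) {
    if (is.null(meta$n_eff)) stop("no N column mapped and meta carries no n_eff")
    tab$n_eff <- meta$n_eff
  }
  if (any(tab$n_eff <= 0, na.rm = TRUE)) stop("n_eff must be positive")
  tab$chrom <- as.character(tab$chrom)

  structure(tab, meta = meta,
            parse_warnings = c(unparseable = n_bad, duplicates = n_dup))
}

#' Write a summary-statistics table as TSV with canonical column names
#'
#' @param table Canonical summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table)[, intersect(canonical_cols, names(table))], path)
  invisible(path)
}

#' Quality-filter a summary-statistics table against a reference panel
#'
#' Applies four filters in a fixed order, each SNP counted against the first
#' rule it violates: (1) restriction to panel SNPs with panel MAF at or
#' above `maf_min`; (2) removal of the MHC interval; (3) removal of
#' `z^2 > z2_max` (strict, so the boundary is retained); (4) removal of SNPs
#' with `n_eff` below `low_n_fraction` times the `low_n_quantile` quantile
#' of `n_eff`, the quantile being computed on the SNPs surviving filters
#' 1-3. Panel MAF overwrites the table's `maf` column for surviving SNPs.
#'
#' @param table Canonical summary-statistics tibble (see [read_sumstats()]).
#' @param panel A [reference_panel()].
#' @param config A [qc_config()].
#' @return A list with `table` (survivors, carrying attribute `M_reference`
#'   = `panel$M`) and `report` (named integer counts; class `qc_report`).
#' @export
qc_filter <- function(table, panel, config = qc_config()) {
  stopifnot(inherits(panel, "reference_panel"), inherits(config, "qc_config"))
  table <- tibble::as_tibble(table)
  if (!nrow(table)) stop("empty summary-statistics table")
  n_input <- nrow(table)

  idx_all <- match(table$snp_id, panel$entries$snp_id)
  in_panel <- !is.na(idx_all)
  removed_not_in_panel <- sum(!in_panel)
  maf_ok <- in_panel & panel$entries$maf[idx_all] >= config$maf_min
  removed_maf <- sum(in_panel & !maf_ok)
  tab <- table[maf_ok, , drop = FALSE]
  keep_panel <- panel$entries
  pidx <- idx_all[maf_ok]
  # MAF comes from the panel (id-only matching; the model is sign-invariant
  # so no allele flipping is attempted); the table's own coordinates are
  # kept, with panel coordinates filling any gaps
  tab$maf <- keep_panel$maf[pidx]
  fill <- is.na(tab$chrom) | is.na(tab$pos)
  tab$chrom[fill] <- keep_panel$chrom[pidx][fill]
  tab$pos[fill] <- keep_panel$pos[pidx][fill]

  in_mhc <- !is.na(tab$chrom) & !is.na(tab$pos) &
    tab$chrom == config$mhc_chrom &
    tab$pos >= config$mhc_start & tab$pos <= config$mhc_end
  removed_mhc <- sum(in_mhc)
  tab <- tab[!in_mhc, , drop = FALSE]

  big_z <- tab$z^2 > config$z2_max
  removed_z2 <- sum(big_z)
  tab <- tab[!big_z, , drop = FALSE]

  low_n <- rep(FALSE, nrow(tab))
  if (nrow(tab)) {
    n_ref <- stats::quantile(tab$n_eff, config$low_n_quantile, names = FALSE)
    low_n <- tab$n_eff < config$low_n_fraction * n_ref
  }
  removed_low_n <- sum(low_n)
  tab <- tab[!low_n, , drop = FALSE]

  if (!nrow(tab)) stop("no SNPs survive QC")

  report <- structure(list(
    n_input = n_input,
    removed_not_in_panel = removed_not_in_panel,
    removed_maf = removed_maf,
    removed_mhc = removed_mhc,
    removed_z2 = removed_z2,
    removed_low_n = removed_low_n,
    n_output = nrow(tab)), class = "qc_report")

  attr(tab, "M_reference") <- panel$M
  attr(tab, "meta") <- attr(table, "meta", exact = TRUE)
  list(table = tab, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "SNPs in,", x$n_output, "out\n")
  cat("  removed: not in panel", x$removed_not_in_panel,
      "| MAF", x$removed_maf, "| MHC", x$removed_mhc,
      "| z^2", x$removed_z2, "| low N", x$removed_low_n, "\n")
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
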