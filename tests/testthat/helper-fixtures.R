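# small builders used across test files; everything is generated in code

# a hand-constructed clean table fully contained in its panel
toy_table <- function(m = 10, n_eff = 1e4, z = NULL) {
  tibble::tibble(
    snp_id = paste0("rs", seq_len(m)),
    chrom = as.character(rep_len(c(1, 2, 3), m)),
    pos = seq_len(m) * 1e6L,
    a1 = "A", a2 = "G",
    maf = rep_len(c(0.1, 0.2, 0.3, 0.4), m),
    beta = NA_real_, se = 1 / sqrt(n_eff),
    z = z %||% rep_len(c(-1.2, 0.4, 2.1, -0.3, 1.5), m),
    n_eff = n_eff,
    p = NA_real_)
}

toy_panel <- function(tab, M = nrow(tab)) {
  reference_panel(tab[, c("snp_id", "chrom", "pos", "maf")], M = M)
}

# quick M2 simulation with a strong, well-identified signal
sim_m2_quick <- function(seed = 1, M = 30000, n = 50000,
                         pi_c = 0.01, sigma2 = 2e-4) {
  simulate_sumstats(
    truth_params("M2", pi_c = pi_c, sigma2 = sigma2, M = M, n = n),
    sim_config(seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
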