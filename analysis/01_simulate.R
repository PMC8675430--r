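#!/usr/bin/env Rscript
# Build the synthetic study roster used throughout the analysis: three trait
# groups whose generative architectures mirror the contrast of interest —
# cortical surface area (few susceptibility SNPs, large effects, modest
# GWAS), cortical thickness (intermediate polygenicity; two of its traits
# carry a second, small-effect sSNP cluster), and neuropsychiatric
# disorders (many sSNPs, small effects, large case-control GWAS). Study
# sizes vary across traits within each group, as they do across real
# consortium releases. Every trait gets its own seeded summary-statistics
# table, truth record and reference panel; tables are written as TSV so the
# downstream steps exercise the same readers a real analysis would.

suppressPackageStartupMessages(library(genarch))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
M <- 50000L   # panel SNPs per trait; desk-scale stand-in for ~1.07M

specs <- list()
add <- function(specs, nm, group, truth, trc) {
  specs[[nm]] <- list(group = group, truth = truth, trc = trc)
  specs
}
sa_n <- c(32000, 36000, 40000, 44000)
th_n <- c(30000, 34000, 38000, 42000)
np_cc <- list(c(40000, 120000), c(50000, 150000),
              c(45000, 160000), c(60000, 180000))
s2_jit <- withr::with_seed(20260929, exp(rnorm(12, 0, 0.15)))
for (i in 1:4) {
  specs <- add(specs, paste0("surface_area_", i), "surface_area",
               truth_params("M2", pi_c = 0.005, sigma2 = 1.5e-4 * s2_jit[i],
                            M = M, n = sa_n[i]),
               trc = 0.93 - 0.02 * i)
}
for (i in 1:4) {
  tr <- if (i <= 2)
    truth_params("M2", pi_c = 0.012, sigma2 = 7e-5 * s2_jit[4 + i],
                 M = M, n = th_n[i])
  else  # two thickness traits carry a second, larger-effect sSNP cluster
    truth_params("M3", pi_c = 0.012, sigma2_1 = 6e-4,
                 sigma2_2 = 4e-5 * s2_jit[4 + i], prop = 0.15,
                 M = M, n = th_n[i])
  specs <- add(specs, paste0("thickness_", i), "thickness", tr,
               trc = 0.88 - 0.02 * i)
}
for (i in 1:4) {
  specs <- add(specs, paste0("neuropsychiatric_", i), "neuropsychiatric",
               truth_params("M2", pi_c = 0.03, sigma2 = 2e-5 * s2_jit[8 + i],
                            M = M, design = "case_control",
                            n_cases = np_cc[[i]][1],
                            n_controls = np_cc[[i]][2]),
               trc = NA_real_)  # reliability covariate is MRI-specific
}

manifest <- list()
for (i in seq_along(specs)) {
  nm <- names(specs)[i]
  sp <- specs[[nm]]
  sim <- simulate_sumstats(sp$truth, sim_config(seed = 20260930 + i))
  write_truth(sim, outdir, prefix = nm)
  readr::write_tsv(sim$panel$entries, file.path(outdir, paste0(nm, "_panel.tsv")))
  entry <- list(group = sp$group,
                design = sp$truth$design,
                n_eff = unique(sim$table$n_eff),
                n_cases = sp$truth$n_cases,
                n_controls = sp$truth$n_controls,
                realized_h2 = sim$realized_h2)
  if (!is.na(sp$trc)) entry$trc <- sp$trc
  manifest[[nm]] <- entry
}
jsonlite::write_json(manifest, file.path(outdir, "roster.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d traits (%d SNPs each) to %s\n", length(specs), M, outdir))
h2 <- vapply(manifest, function(m) m$realized_h2, numeric(1))
grp <- vapply(manifest, function(m) m$group, character(1))
cat("realized h2 by group:\n")
print(round(tapply(h2, grp, mean), 4))
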