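#!/usr/bin/env Rscript
# Correlation screens and contingency checks over the fitted roster:
# Pearson correlations of polygenicity/discoverability/heritability with
# the test-retest covariate and with each other, a Fisher contrast of
# best-fit model counts between the two cortical groups, and a Welch test
# of the study sizes behind the cortical vs behavioral groups.

suppressPackageStartupMessages(library(genarch))

run <- "results/run"
stopifnot(dir.exists(run))  # run analysis/02_fit_architectures.R first
metrics <- readr::read_tsv(file.path(run, "metrics.tsv"),
                           show_col_types = FALSE)
cors <- readr::read_tsv(file.path(run, "correlations.tsv"),
                        show_col_types = FALSE)

cat("Correlation screens from the pipeline bundle:\n")
print(as.data.frame(cors), digits = 3)

# best-fit model counts by cortical group
cortical <- metrics[metrics$group %in% c("surface_area", "thickness"), ]
counts <- table(cortical$group, cortical$model)
cat("\nBest-fit model counts (cortical groups):\n")
print(counts)
if (all(dim(counts) == c(2, 2))) {
  cat(sprintf("Fisher two-sided p = %.3f\n", fisher_exact_2x2(counts)))
} else {
  cat("one model class fit every trait; contingency test degenerate\n")
}

# study sizes: cortical vs behavioral (Welch)
neff <- metrics$n_eff_mean
is_cortical <- metrics$group %in% c("surface_area", "thickness")
wt <- welch_t_test(neff[is_cortical], neff[!is_cortical])
cat(sprintf("\nWelch t test of study sizes (cortical vs behavioral): t = %.2f, df = %.1f, p = %.3g\n",
            wt$t, wt$df, wt$p))

# within-group heterogeneity of polygenicity across surface-area traits
sa <- metrics[metrics$group == "surface_area" & metrics$status == "ok", ]
M <- 50000
wg <- within_group_heterogeneity(sa$n_ssnp, sa$se_pi * M)
cat(sprintf("\nWithin-group heterogeneity of surface-area polygenicity: I2 = %.0f%%, p = %.3g\n",
            100 * wg$I2, wg$p))
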