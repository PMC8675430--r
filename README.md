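# genarch

Estimating the common-variant genetic architecture of complex traits from
GWAS summary statistics, and comparing architectures across trait groups.

## The problem

Are brain-structure measures "easier" GWAS targets than the neuropsychiatric
disorders they are hypothesized to underlie? That question reduces to two
architecture parameters per trait, estimable from public summary statistics
alone:

- **polygenicity** (π<sub>c</sub>): the proportion of reference SNPs that are
  *susceptibility SNPs* (sSNPs) — LD-independent loci with a nonzero effect,
  not necessarily genome-wide significant. π<sub>c</sub> × M predicts the
  total sSNP count against a reference panel of M SNPs.
- **discoverability**: the spread of the sSNP effect-size distribution,
  summarized as the median absolute effect (the effect size that half of all
  sSNPs exceed in magnitude).

A trait with fewer sSNPs of larger effect needs smaller samples for the same
discovery yield; the package also projects the **sample size at which
genome-wide-significant SNPs would explain 99% of SNP heritability**.

## The model

For an effectively LD-independent SNP *j* with effective sample size
*n<sub>j</sub>*, the z-score is modelled marginally as a point-normal
mixture on the standardized effect scale:

```
M2:  z_j ~ (1 − π_c) N(0, a) + π_c N(0, a + n_j σ²)
M3:  z_j ~ (1 − π_c) N(0, a) + π_c [ prop · N(0, a + n_j σ₁²)
                                     + (1 − prop) · N(0, a + n_j σ₂²) ]
```

with `a` an intercept absorbing stratification inflation (1 = none). Fits
are by bounded maximum likelihood (a monotone generalized-EM mode is also
provided), standard errors by inverse observed Hessian, model choice by the
rule *use M2 if σ₁²/σ₂² < 5 or BIC(M2) < BIC(M3)*. Derived quantities:

- sSNP count `π_c · M` with plug-in 95% CI;
- median absolute sSNP effect: the upper quartile of N(0, σ²) for M2, a
  grid search over `seq(0, 0.02, length = 200)` for the M3 mixture, with
  clamped plug-in CIs;
- heritability `h² = M · π_c · E[β²]`;
- GV%: the percentage of h² carried by SNPs whose two-sided test passes
  5×10⁻⁸ at sample size n, by Gauss–Hermite quadrature over the effect
  distribution, swept across n = 50 K … 200 M.

Trait groups are compared with fixed-effect (inverse-variance) pooling and
between-group heterogeneity (Cochran's Q, I², chi-square p), with
Benjamini–Hochberg FDR across the configured family of group pairs.

A seeded synthetic-data module generates summary statistics with known truth
(point-normal effects, stratification inflation, case-control effective
sample sizes, MHC/low-N/outlier artifacts) so the whole pipeline is testable
without any download.

## Worked example

```r
library(genarch)

truth <- truth_params("M2", pi_c = 0.01, sigma2 = 2e-4, M = 50000, n = 50000)
sim   <- simulate_sumstats(truth, sim_config(seed = 3))
qc    <- qc_filter(sim$table, sim$panel, qc_config())
fit   <- fit_mixture(qc$table, "M2")
fit
#> M2 mixture fit: 49833 SNPs (M = 50000 reference)
#>   pi_c = 0.0104  sigma2 = 0.0001716  a = 1.012
#>   loglik = -72433.28  BIC = 144899.01  converged = TRUE  SEs available

architecture_metrics(fit, trait = "toy", group = "demo")[
  , c("n_ssnp", "n_ssnp_lo", "n_ssnp_hi", "median_abs_effect", "h2")]
#> # A tibble: 1 × 5
#>   n_ssnp n_ssnp_lo n_ssnp_hi median_abs_effect     h2
#>    <dbl>     <dbl>     <dbl>             <dbl>  <dbl>
#> 1   520.      379.      661.           0.00883 0.0892

required_n(fit, step = 1e6, grid_start = 1e6)
#> n required for GV% >= 99%: 2e+06
```

Read: ~520 of the 50,000 panel SNPs are predicted to carry an effect
(95% CI 379–661; truth was 500), the median sSNP moves the phenotype by
|r| ≈ 0.009 per allele on the correlation scale, the model-implied SNP
heritability is 0.089 (truth 0.1), and a GWAS of ~2 M individuals would be
needed before genome-wide-significant SNPs explain 99% of that
heritability.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full study on synthetic
data and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | 12-trait roster in three groups (surface-area-like, thickness-like, neuropsychiatric-like case-control), written as TSV with truth records |
| `02_fit_architectures.R` | QC → M2/M3 fits → selection → metrics → GV% projections → group heterogeneity with FDR |
| `03_winners_curse.R` | refits one study at emulated smaller sizes; CIs overlap and SEs shrink with n |
| `04_covariate_screens.R` | Pearson screens (reliability covariate, polygenicity vs discoverability), best-fit-model contingency, Welch test of study sizes |

On the shipped configuration the pipeline finds what it was built to find:
the surface-area-like group has the fewest predicted sSNPs and the largest
median effects, the neuropsychiatric-like group the reverse (heterogeneity
FDR ≈ 3×10⁻¹⁰ and 1×10⁻²⁶ for the two contrasts), and the projected sample
size for complete heritability is ~1.4–2.1 M for the surface-area-like
traits against ~13–16 M for the neuropsychiatric-like ones.

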