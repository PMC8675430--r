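Package: genarch
Title: Polygenicity and Discoverability of Complex Traits from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the common-variant genetic architecture of complex
    traits from GWAS summary statistics using point-normal mixture models
    of SNP effect sizes. Fits two- and three-component mixtures to z-scores
    of effectively LD-independent SNPs, selects between them by BIC and a
    variance-ratio rule, and derives polygenicity (the expected number of
    susceptibility SNPs), discoverability (the median absolute effect size
    of susceptibility SNPs), heritability, and the sample size a future
    GWAS would need for genome-wide-significant SNPs to explain 99% of
    heritability. Includes fixed-effect heterogeneity tests for comparing
    trait groups, a quality-control workflow for harmonizing summary
    statistics against a reference panel, and a seeded generator of
    synthetic summary statistics with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml
Config/testthat/edition: 3
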