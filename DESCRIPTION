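Package: grsmr
Title: Genetic-Risk-Score Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization built on weighted
    genetic-risk-score (GRS) instruments. Reads instrument weight tables and
    per-outcome GWAS summary statistics, harmonizes alleles with proxy-SNP
    resolution, computes the closed-form inverse-variance-weighted causal
    estimate with Wald inference, instrument-strength F-statistics, Cochran-Q
    heterogeneity tests with stepwise pleiotropy pruning and leave-one-out
    sensitivity analysis, an individual-level polygenic-risk-score stage
    (threshold scoring, covariate-adjusted logistic association, Nagelkerke
    delta R-squared, fixed-effects meta-analysis across cohorts), a
    multi-outcome panel driver with Bonferroni significance tiers, and a
    synthetic-data generator that emulates the assumed statistical structure
    of consortium summary statistics and case-control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
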