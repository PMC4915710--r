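#!/usr/bin/env Rscript
# Individual-level validation stage: simulates 12 case-control cohorts with a
# protective exposure effect on the liability scale, scores each individual
# at five exposure p-value thresholds, fits the covariate-adjusted logistic
# association per cohort, and pools cohorts by fixed-effects IVW
# meta-analysis. Writes results/prs_threshold_scan.tsv.
# Cohorts are regenerated from seeds (dosage matrices are not persisted).

suppressPackageStartupMessages(library(grsmr))

seed <- 2026L
n_cohorts <- 12
cohorts <- lapply(seq_len(n_cohorts), function(k) {
  simulate_cohort(n_individuals = 1500, m_snps = 18, seed = seed + k,
                  alpha_true = -0.15, grs_r2_target = 0.05,
                  case_fraction = 0.45, n_pcs = 10,
                  cohort_id = sprintf("cohort_%02d", k))
})

scan <- prs_threshold_scan(cohorts)
dir.create("results", showWarnings = FALSE)
readr::write_delim(scan, file.path("results", "prs_threshold_scan.tsv"),
                   delim = "\t", na = ".")

cat(sprintf("PRS threshold scan over %d cohorts (%d individuals total):\n",
            n_cohorts, sum(vapply(cohorts, function(c) length(c$phenotype),
                                  numeric(1)))))
for (i in seq_len(nrow(scan))) {
  cat(sprintf("  p <= %-6g n_snps = %2d  pooled OR/SD %.3f (%.3f-%.3f), p = %.2g, dR2 = %.2g\n",
              scan$threshold[i], scan$n_snps[i], scan$or_per_sd[i],
              scan$ci_low[i], scan$ci_high[i], scan$p[i], scan$delta_r2[i]))
}
cat("A protective liability effect shows as pooled OR per SD below 1 at every threshold.\n")
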