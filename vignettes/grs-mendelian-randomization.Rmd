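---
title: "GRS-based Mendelian randomization from summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GRS-based Mendelian randomization from summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmr)
```

# The problem

Observational associations between a circulating biomarker — here the
inflammation marker C-reactive protein (CRP) — and disease cannot separate
cause from consequence or confounding. Mendelian randomization (MR) uses
genetic variants as instrumental variables: because alleles are assigned at
conception, a variant that raises lifelong CRP levels is (under the
instrumental-variable assumptions) free of the confounding and reverse
causation that afflict the observational association. `grsmr` implements a
two-sample MR workflow in which the instrument is a weighted genetic risk
score (GRS) — a set of uncorrelated SNPs with known per-allele effects
$\omega_j$ on the natural-log exposure — and the outcome side is a table of
per-SNP effects $\beta_j$ (log odds ratios for diseases, trait units
otherwise) with standard errors $se_{\beta j}$ taken from consortium GWAS
summary statistics.

The three instrumental-variable assumptions are: the SNPs are associated
with the exposure (checked by the F-statistic); they are independent of
confounders of the exposure–outcome relation (granted by Mendelian
inheritance, up to population structure handled upstream); and they affect
the outcome only through the exposure (the exclusion restriction, probed by
the heterogeneity machinery below).

# The causal estimator

For uncorrelated SNPs, regressing the outcome on an additive GRS using only
summary statistics gives the closed-form inverse-variance-weighted (IVW)
estimator

$$\hat\alpha \;=\; \frac{\sum_j \omega_j \beta_j\, se_{\beta j}^{-2}}
                        {\sum_j \omega_j^2\, se_{\beta j}^{-2}},
\qquad
se_{\hat\alpha} \;=\; \sqrt{\frac{1}{\sum_j \omega_j^2\, se_{\beta j}^{-2}}},$$

the slope (and fixed-effect standard error) of the weighted least-squares
regression of $\beta$ on $\omega$ through the origin with weights
$se_\beta^{-2}$. The test suite holds this equivalence to $10^{-10}$
relative tolerance against an independent `lm()` oracle on random instances.
$\hat\alpha$ is the effect of a one-unit increase in the ln-exposure; for
binary outcomes it is a log odds ratio and is presented as
$e^{\hat\alpha}$ with a 95% CI using the multiplier $\Phi^{-1}(0.975) =
1.959964$ (not 1.96; rounding happens only at presentation). Inference is a
large-sample two-sided Wald test against the standard normal — the standard
choice for summary-statistics MR; no small-sample correction is applied.

One unit of ln-exposure is a large change; since $0.1$ ln-units is a
symmetric 10% ("10 sympercent") change in the exposure itself,
`rescale_effect(e, 0.1)` converts an estimate to the per-10-s% presentation.
The canonical internal scale is always per unit ln-exposure and conversion
is explicit, so estimates cannot be silently double-scaled; the Wald z and
p-value are invariant under the conversion because $\alpha$ and
$se_\alpha$ scale together.

## Instrument strength

Weak instruments bias two-sample estimates toward the null. The
first-stage strength is summarized by

$$F \;=\; \frac{R^2\,(n - 1 - K)}{(1 - R^2)\,K},$$

with $R^2$ the proportion of exposure variance explained by the GRS, $n$
the exposure-GWAS sample size, and $K = 1$ for a single score. $F > 10$ is
the conventional comfort threshold. The two scores modeled here explain
roughly 2% (a 4-SNP score confined to the *CRP* gene) and 5% (an 18-SNP
genome-wide score) of ln-CRP variance, which at consortium sample sizes
gives $F$ in the tens to thousands:

```{r}
f_statistic(0.05, n = 79845, k = 1)  # 18-SNP score, schizophrenia consortium
f_statistic(0.02, n = 1566, k = 1)   # 4-SNP score, smallest outcome set
```

# Pleiotropy: heterogeneity, pruning, leave-one-out

A SNP that affects the outcome through a pathway other than the exposure
violates the exclusion restriction, and its per-SNP ratio
$\beta_j/\omega_j$ drifts away from the common slope. We quantify this with
a Cochran-style Q statistic, the weighted residual sum of squares about the
fitted slope:

$$Q = \sum_j se_{\beta j}^{-2}\,(\beta_j - \hat\alpha\,\omega_j)^2
\;\sim\; \chi^2_{M-1} \text{ under homogeneity},$$

with $M - 1$ degrees of freedom because one parameter (the slope) is
estimated. Heterogeneity is declared at an uncorrected $p < 0.05$ — a
deliberately conservative trigger, since heterogeneity can also arise from
sources other than pleiotropy.

`prune_heterogeneity()` then removes SNPs stepwise: at each step the SNP
with the **largest Q contribution at the current fit** is removed (ties
broken by rsid order, making the procedure fully deterministic), the
estimate is **refitted**, and the loop stops as soon as $p_{het} \ge 0.05$.
Refitting after every removal matches the logic of repeating the analysis
on the reduced score; ranking by Q contribution is the deterministic
reading of "stepwise removal" and, on data with planted outliers, removes
the planted SNPs first (held at $\ge 90\%$ of replicates in the acceptance
suite). Pruning never goes below 2 SNPs — the last point at which Q has a
degree of freedom; if the floor is reached while still heterogeneous the
trace is flagged rather than silently truncated.

`leave_one_out()` refits the estimate once per excluded SNP; a result that
survives every exclusion is not driven by a single (possibly pleiotropic)
variant.

# Harmonization and proxies

Instrument and outcome tables are joined by rsid. Allele alignment is by
nucleotide identity only: if the outcome record's effect/other alleles are
swapped relative to the instrument, $\beta$ is sign-flipped; if the allele
sets match neither orientation the SNP is dropped with reason
`allele_mismatch`. No strand inference is attempted — the consortium data
this models were pre-aligned, and a silent strand flip is the dominant
error mode, so strictness plus flags beats guessing. Palindromic (A/T,
C/G) SNPs are retained but flagged by default; `drop_palindromic = TRUE`
drops them.

A SNP absent from the outcome table may be replaced by a proxy in high
linkage disequilibrium: eligibility requires $r^2 > 0.9$ (strict
inequality), the eligible proxy with the highest $r^2$ wins, and exact
$r^2$ ties go to the proxy nearest the original SNP (then rsid order).
Whether proxies are sought at all is the caller's choice — passing no proxy
table simply drops missing SNPs, which is the default behaviour since the
reference analyses dropped the three score SNPs absent from the
schizophrenia consortium rather than substituting proxies. Proxy records
are assumed pre-oriented (the proxy's $\beta$ reported on the allele
tagging the instrument SNP's effect allele); no LD-phase allele mapping is
attempted, a known limitation.

Two properties pin the implementation down: harmonization is idempotent,
and jointly flipping every outcome record's alleles and $\beta$ sign leaves
the harmonized object (hence $\hat\alpha$) unchanged.

# Multiple testing over the outcome panel

The reference design tests one GRS against each of 32 independent outcome
sample sets, one test per set, so the Bonferroni denominator is 32 (not
scores × outcomes): threshold $0.05/32 = 0.0016$ at 4-decimal
presentation. Results are tiered with inclusive boundaries: $p \le 0.0016$
statistically significant, $0.0016 < p \le 0.05$ nominal, $p > 0.05$ no
association. `run_panel()` applies the whole pipeline per (GRS, outcome)
pair, then re-runs every heterogeneous analysis through pruning and appends
the post-pruning rows; per-outcome failures are recorded and skipped so one
malformed table cannot abort a panel.

The association p-value column is named `p_assoc` throughout: the reference
tables label it a goodness-of-fit p-value while printing a separate
heterogeneity column, and the unambiguous name avoids conflating the causal
Wald test with the Q test.

# The individual-level PRS stage

The summary-statistics result for a flagship outcome is validated on
individual-level data: a polygenic risk score per individual,
$PRS_i = \sum_j \omega_j d_{ij}$ over SNPs whose exposure-association
p-value passes a threshold (the scan uses $10^{-4}, 0.001, 0.01, 0.05,
0.1$), z-standardized **within cohort** so effects are per 1 SD of the
score. Each cohort is analysed separately — logistic regression of case
status on the score with up to ten principal components as covariates
(IRLS, tolerance $10^{-8}$, $\le 100$ iterations) — and cohorts are pooled
by fixed-effects IVW meta-analysis: $b = \sum w_i b_i / \sum w_i$,
$se = (\sum w_i)^{-1/2}$, $w_i = se_i^{-2}$. Within-cohort standardization
followed by meta-analysis mirrors per-cohort GWAS practice;
cross-cohort standardization is deliberately not used. The variance
explained by the score is the Nagelkerke (max-rescaled Cox–Snell)
pseudo-$R^2$ increment of the full model over the covariates-only null:

$$R^2_{CS} = 1 - e^{2(\ell_0 - \ell_1)/n}, \qquad
  R^2_N = \frac{R^2_{CS}}{1 - e^{2\ell_0/n}}.$$

How sub-threshold exposure SNPs were selected or LD-clumped upstream is
outside the model: the scan operates on whatever SNP set and exposure
p-values are supplied. Family structure (the reference excluded
parent-offspring trios) is likewise absent from the data model.

# The synthetic-data generator

No consortium data ship with the package; `simulate_summary()` and
`simulate_cohort()` generate inputs with exactly the statistical structure
the estimator assumes, so every stage is testable without a download.

For summary statistics: effect-allele frequencies $f_j \sim U(0.1, 0.5)$;
true weights drawn and jointly rescaled so
$\sum_j 2 f_j (1-f_j)\, \omega_j^2 = R^2$ on a unit-variance ln-exposure;
reported weights add noise with the standard per-allele GWAS approximation
$se_{\omega j} = (2 f_j (1-f_j)\, n_{exp})^{-1/2}$; outcome effects
$\beta_j \sim N(\alpha\,\omega_j + \delta_j,\; se_{\beta j})$ with
$se_{\beta j} = (2 f_j (1-f_j)\, n_{eff})^{-1/2}$ and
$n_{eff} = n_{cases} n_{controls} / n_{total}$ for case-control outcomes.
Direct (pleiotropic) effects $\delta_j \sim N(0, sd_{pleio})$ are planted
on a seeded random subset. Exposure-side and outcome-side noise run on
distinct deterministic sub-streams of the seed, reproducing the two-sample
design in which the weights and the outcome statistics come from
non-overlapping samples.

Default conditions are fixed once and encode the reference study:
$m = 18$ SNPs, $R^2 = 0.05$ (0.02 for the gene-only score),
$n_{exp} = 66{,}185$ (the scale of the CRP meta-GWAS behind the weights),
case-control sizes 34,241/45,604 (the schizophrenia consortium). The
planted-pleiotropy calibration uses $sd_{pleio} = 0.2$, about 17 times the
per-SNP $se_\beta$ at those sample sizes — comfortably in the
"large direct effect" regime the pruning test targets.

For cohorts: dosages $\sim \text{Binomial}(2, f_j)$, a latent ln-exposure
equal to the true-weight score plus Gaussian noise topping it up to unit
variance (so the score explains exactly the requested $R^2$ in
expectation), standard-normal PCs with liability effects of SD 0.1, and a
logistic case probability whose intercept is solved numerically
(`uniroot`, tolerance $10^{-10}$) so the expected case fraction matches the
target (0.45, the case-control consortium's ratio). The PRS-stage
simulations use 12 cohorts of 1,500 individuals — the package's chosen
desk-scale rendering of a 36-cohort, 56,605-subject consortium; large
enough that a protective liability effect of $-0.15$ per ln-unit (OR
$\approx 0.86$) is recovered directionally in $\ge 95\%$ of replicates,
small enough that the whole calibration runs in seconds.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium between
instrument SNPs (the scores are built from uncorrelated SNPs by design, but
real proxies are correlated); population structure beyond independent PC
covariates; sample overlap between exposure and outcome GWAS; allele
frequency and effect-size spectra of real GWAS; winner's-curse in weight
estimation; and case-control ascertainment effects on $se_\beta$ beyond
the effective-sample-size approximation.

# Monte-Carlo problem sizes and calibration bands

The acceptance checks use 1,000 replicates for null rejection rates (bands
$[0.03, 0.07]$ at the 5% level, i.e. ±4 binomial SDs) and 95% CI coverage
(band $[0.93, 0.97]$), 200 replicates for pruning recovery ($\ge 90\%$ of
replicates must remove at least two of three planted SNPs before any clean
SNP), and 100 replicates of the 12-cohort meta-analysis for direction
recovery ($\ge 95\%$ pooled OR < 1). These sizes were chosen so each band
is several Monte-Carlo standard errors wide while the full suite stays
fast.

# Known limitations

* The estimator treats the weights $\omega_j$ as known; their estimation
  error (small at $n_{exp} \approx 66{,}000$) attenuates $\hat\alpha$ by
  well under 1% at these settings but is not corrected.
* Q-based pruning is conservative and can remove SNPs whose heterogeneity
  has non-pleiotropic causes; it is an outlier screen, not a test of the
  exclusion restriction.
* No MR-Egger, weighted-median or mode-based estimators, and no
  multivariable MR: the package implements the GRS/IVW design faithfully
  rather than the wider modern MR toolbox.
* Proxy substitution trusts the supplied LD table and its orientation;
  remote LD lookup and imputation are out of scope.
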