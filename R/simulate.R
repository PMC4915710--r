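# Synthetic summary-level and individual-level inputs with the statistical
# structure the two-sample GRS estimator assumes: independent (uncorrelated)
# instrument SNPs, per-allele GWAS standard errors 1/sqrt(2 f (1-f) n_eff),
# independent exposure- and outcome-side noise, and optional direct
# (pleiotropic) outcome effects on a planted subset of SNPs.

# Sub-seeds keep the three noise streams (latent truth, exposure-side noise,
# outcome-side noise) on distinct deterministic streams, mirroring the
# two-sample design. Callers pass one seed < 2^31 - 3.
.substream <- function(seed, offset) {
  s <- as.integer(seed) + as.integer(offset)
  set.seed(s)
  invisible(s)
}

#' Simulate two-sample GWAS summary statistics for a GRS instrument
#'
#' Generates an instrument weight table and a matching outcome
#' summary-statistics table under a known truth. Effect-allele frequencies
#' are Uniform over `eaf_range`; true per-allele weights are drawn and then
#' jointly rescaled so the GRS explains `r2_target` of a unit-variance
#' ln-exposure; reported weights add estimation noise with
#' `se_omega = 1/sqrt(2 f (1-f) n_exposure)`. Outcome effects are
#' `beta_j ~ N(alpha_true * omega_true_j + delta_j, se_beta_j)` with
#' `se_beta_j = 1/sqrt(2 f (1-f) n_eff)`, `n_eff = n_cases n_controls /
#' n_total` for binary outcomes and `n_total` otherwise. A seeded random
#' subset of `round(pleiotropy_fraction * m)` SNPs receives a direct outcome
#' effect `delta_j ~ N(0, pleiotropy_sd)`.
#'
#' @param m_snps Number of instrument SNPs (default 18).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param eaf_range Interval for effect-allele frequencies
#'   (default `c(0.1, 0.5)`).
#' @param n_exposure Exposure-GWAS sample size (default 66185, the scale of
#'   the reference CRP meta-GWAS).
#' @param r2_target Exposure variance explained by the GRS (default 0.05, the
#'   18-SNP genome-wide score; the 4-SNP gene score corresponds to 0.02).
#' @param alpha_true True causal effect per unit ln-exposure (default 0).
#' @param pleiotropy_fraction Fraction of SNPs given direct outcome effects.
#' @param pleiotropy_sd SD of the direct effects (default 0.2).
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param n_cases,n_controls Case/control counts for binary outcomes
#'   (defaults 34241/45604, the schizophrenia consortium scale).
#' @param n_total Sample size for quantitative outcomes.
#' @param outcome_name Label for the outcome table.
#' @return A list with `instrument` (weights tibble), `outcome` (summary-stats
#'   tibble), and `truth` (list holding all latent values, including
#'   `omega_true`, `delta`, `pleiotropic_rsids`, `alpha_true`).
#' @export
simulate_summary <- function(m_snps = 18, seed = 1, eaf_range = c(0.1, 0.5),
                             n_exposure = 66185, r2_target = 0.05,
                             alpha_true = 0, pleiotropy_fraction = 0,
                             pleiotropy_sd = 0.2,
                             outcome_type = c("binary", "quantitative"),
                             n_cases = 34241, n_controls = 45604,
                             n_total = NULL, outcome_name = "synthetic_outcome") {
  outcome_type <- match.arg(outcome_type)
  stopifnot(m_snps >= 1, pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            r2_target > 0, r2_target < 1, pleiotropy_sd > 0,
            eaf_range[1] > 0, eaf_range[2] <= 0.5, n_exposure > 1)

  # latent stream: frequencies, true weights, planted subset
  .substream(seed, 0L)
  eaf <- stats::runif(m_snps, eaf_range[1], eaf_range[2])
  omega_raw <- abs(stats::rnorm(m_snps, 0, 1))
  # scale so var(GRS) = sum 2 f (1-f) omega^2 = r2_target on unit-variance exposure
  het <- 2 * eaf * (1 - eaf)
  omega_true <- omega_raw * sqrt(r2_target / sum(het * omega_raw^2))
  n_pleio <- round(pleiotropy_fraction * m_snps)
  pleio_idx <- if (n_pleio > 0) sort(sample.int(m_snps, n_pleio)) else integer(0)
  delta <- numeric(m_snps)
  if (n_pleio > 0) delta[pleio_idx] <- stats::rnorm(n_pleio, 0, pleiotropy_sd)

  # exposure-side stream: estimation noise on the weights
  .substream(seed, 1L)
  omega_se <- 1 / sqrt(het * n_exposure)
  omega_hat <- stats::rnorm(m_snps, omega_true, omega_se)

  # outcome-side stream
  .substream(seed, 2L)
  if (outcome_type == "binary") {
    if (is.null(n_cases) || is.null(n_controls)) {
      stop("binary outcomes need n_cases and n_controls", call. = FALSE)
    }
    n_total_out <- n_cases + n_controls
    n_eff <- n_cases * n_controls / n_total_out
  } else {
    if (is.null(n_total)) stop("quantitative outcomes need n_total", call. = FALSE)
    n_total_out <- n_total
    n_eff <- n_total
  }
  se_beta <- 1 / sqrt(het * n_eff)
  beta <- stats::rnorm(m_snps, alpha_true * omega_true + delta, se_beta)

  rsid <- sprintf("rs%07d", seq_len(m_snps))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m_snps, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, c(a, .complement[[a]])), 1),
               character(1))

  instrument <- tibble::tibble(
    rsid = rsid, chrom = as.character(1 + (seq_len(m_snps) - 1) %% 22),
    pos = 1e6 * seq_len(m_snps), effect_allele = ea, other_allele = oa,
    omega = omega_hat, omega_se = omega_se, eaf = eaf,
    locus = sprintf("LOCUS%02d", seq_len(m_snps)))
  outcome <- tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    beta = beta, se_beta = se_beta, n_total = n_total_out,
    n_cases = if (outcome_type == "binary") n_cases else NA_integer_,
    n_controls = if (outcome_type == "binary") n_controls else NA_integer_)
  attr(outcome, "outcome_name") <- outcome_name
  attr(outcome, "outcome_type") <- outcome_type

  list(instrument = instrument, outcome = outcome,
       truth = list(eaf = eaf, omega_true = omega_true, omega_se = omega_se,
                    delta = delta, pleiotropic_rsids = rsid[pleio_idx],
                    alpha_true = alpha_true, r2_target = r2_target,
                    se_beta = se_beta, n_eff = n_eff, seed = seed))
}

#' Simulate an individual-level case-control cohort for the PRS stage
#'
#' Dosages are Binomial(2, EAF); the latent ln-exposure is the weighted
#' dosage sum plus Gaussian noise scaled so the score explains
#' `grs_r2_target` of the exposure variance; principal components are
#' standard normal with liability effects of SD `pc_effect_sd`; case
#' probability is logistic in `alpha_true * exposure + PC effects` with an
#' intercept solved so the expected case fraction equals `case_fraction`.
#'
#' @param n_individuals Cohort size (default 1500).
#' @param m_snps Number of score SNPs (default 18).
#' @param seed Integer seed.
#' @param grs_r2_target Exposure variance explained by the score
#'   (default 0.05).
#' @param alpha_true Causal effect of the ln-exposure on the liability
#'   (log-odds) scale.
#' @param case_fraction Expected proportion of cases (default 0.45).
#' @param n_pcs Number of principal-component covariates (default 10).
#' @param pc_effect_sd SD of per-PC liability effects (default 0.1).
#' @param eaf_range Interval for allele frequencies.
#' @param n_exposure Sample size behind the reported weights / exposure
#'   p-values in `snp_meta`.
#' @param cohort_id Cohort label.
#' @return A `cohort_data` with a `truth` attribute (latent exposure, true
#'   weights, PC effects, intercept).
#' @export
simulate_cohort <- function(n_individuals = 1500, m_snps = 18, seed = 1,
                            grs_r2_target = 0.05, alpha_true = 0,
                            case_fraction = 0.45, n_pcs = 10,
                            pc_effect_sd = 0.1, eaf_range = c(0.1, 0.5),
                            n_exposure = 66185, cohort_id = "synthetic_cohort") {
  stopifnot(grs_r2_target > 0, grs_r2_target < 1, n_individuals > 10,
            case_fraction > 0, case_fraction < 1, n_pcs >= 0, n_pcs <= 10)

  .substream(seed, 0L)
  eaf <- stats::runif(m_snps, eaf_range[1], eaf_range[2])
  het <- 2 * eaf * (1 - eaf)
  omega_raw <- abs(stats::rnorm(m_snps, 0, 1))
  omega_true <- omega_raw * sqrt(grs_r2_target / sum(het * omega_raw^2))
  omega_se <- 1 / sqrt(het * n_exposure)

  .substream(seed, 1L)
  omega_hat <- stats::rnorm(m_snps, omega_true, omega_se)
  z_exp <- omega_hat / omega_se
  exposure_p <- 2 * pnorm(-abs(z_exp))

  .substream(seed, 2L)
  dosages <- matrix(stats::rbinom(n_individuals * m_snps, 2,
                                  rep(eaf, each = n_individuals)),
                    nrow = n_individuals)
  colnames(dosages) <- sprintf("rs%07d", seq_len(m_snps))
  score_part <- as.vector(dosages %*% omega_true)
  # score variance is grs_r2_target by construction; residual noise tops the
  # exposure up to unit variance
  exposure <- score_part + stats::rnorm(n_individuals, 0, sqrt(1 - grs_r2_target))
  pcs <- if (n_pcs > 0) {
    matrix(stats::rnorm(n_individuals * n_pcs), nrow = n_individuals,
           dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  } else {
    matrix(numeric(0), nrow = n_individuals, ncol = 0)
  }
  pc_effects <- if (n_pcs > 0) stats::rnorm(n_pcs, 0, pc_effect_sd) else numeric(0)
  eta_no_int <- alpha_true * exposure +
    (if (n_pcs > 0) as.vector(pcs %*% pc_effects) else 0)
  # intercept solving the target case fraction for this cohort's linear terms
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + eta_no_int)) - case_fraction,
    interval = c(-30, 30), tol = 1e-10)$root
  phenotype <- stats::rbinom(n_individuals, 1, stats::plogis(intercept + eta_no_int))
  if (length(unique(phenotype)) < 2) {
    # pathological draw at tiny n; force one flip for downstream usability
    phenotype[1] <- 1L - phenotype[1]
  }

  snp_meta <- tibble::tibble(rsid = colnames(dosages),
                             effect_allele = "A", omega = omega_hat,
                             exposure_p = exposure_p)
  co <- cohort_data(cohort_id, dosages, phenotype, pcs, snp_meta)
  attr(co, "truth") <- list(eaf = eaf, omega_true = omega_true,
                            exposure = exposure, pc_effects = pc_effects,
                            intercept = intercept, alpha_true = alpha_true,
                            seed = seed)
  co
}
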