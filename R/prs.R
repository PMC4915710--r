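# Individual-level polygenic-risk-score stage: threshold scoring, logistic
# association with principal-component covariates, Nagelkerke delta-R2, and
# fixed-effects meta-analysis across cohorts.

#' Construct a cohort container for the PRS stage
#'
#' @param cohort_id Cohort label.
#' @param dosages Individuals-by-SNPs numeric matrix of allele dosages in
#'   \[0, 2\]; column names are rsids.
#' @param phenotype Binary vector (1 = case), one per individual.
#' @param pcs Individuals-by-c matrix of principal-component covariates
#'   (c <= 10; may have zero columns).
#' @param snp_meta Tibble with one row per dosage column: `rsid`,
#'   `effect_allele`, `omega` (weight on the ln-exposure), `exposure_p`
#'   (exposure-association p-value used for thresholding).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(cohort_id, dosages, phenotype, pcs, snp_meta) {
  dosages <- as.matrix(dosages)
  pcs <- as.matrix(pcs)
  phenotype <- as.integer(phenotype)
  if (nrow(dosages) != length(phenotype) ||
      (ncol(pcs) > 0 && nrow(pcs) != length(phenotype))) {
    stop("row counts of dosages, phenotype and pcs must agree", call. = FALSE)
  }
  if (ncol(dosages) != nrow(snp_meta)) {
    stop("snp_meta must have one row per dosage column", call. = FALSE)
  }
  if (any(dosages < 0 | dosages > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (!all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be binary 0/1", call. = FALSE)
  }
  if (ncol(pcs) > 10) stop("at most 10 principal components are supported", call. = FALSE)
  structure(list(cohort_id = as.character(cohort_id), dosages = dosages,
                 phenotype = phenotype, pcs = pcs,
                 snp_meta = tibble::as_tibble(snp_meta)),
            class = "cohort_data")
}

#' Compute a standardized polygenic risk score at a p-value threshold
#'
#' The raw score for individual i is \eqn{\sum_j \omega_j d_{ij}} over the
#' SNPs whose exposure-association p-value is at or below `threshold`; the
#' returned score is z-standardized within the cohort (mean 0, SD 1), so
#' downstream odds ratios are per 1 SD of the score.
#'
#' @param cohort A `cohort_data`.
#' @param threshold Exposure p-value inclusion threshold.
#' @return Standardized numeric score vector with attributes `n_snps` and
#'   `threshold`.
#' @export
compute_prs <- function(cohort, threshold) {
  stopifnot(inherits(cohort, "cohort_data"))
  keep <- which(cohort$snp_meta$exposure_p <= threshold)
  if (length(keep) == 0) {
    stop(sprintf("no SNPs pass the exposure p-value threshold %g", threshold),
         call. = FALSE)
  }
  raw <- as.vector(cohort$dosages[, keep, drop = FALSE] %*%
                     cohort$snp_meta$omega[keep])
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("degenerate score: zero variance across individuals", call. = FALSE)
  }
  score <- (raw - mean(raw)) / s
  attr(score, "n_snps") <- length(keep)
  attr(score, "threshold") <- threshold
  score
}

#' Logistic association of a standardized PRS with case status
#'
#' Fits `phenotype ~ score + PCs` by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations). The score
#' coefficient is the log-OR per 1 SD of the PRS; Wald inference and a 95%
#' CI are attached, along with the Nagelkerke pseudo-R-squared increment of
#' the full model over the covariates-only null model.
#'
#' @param cohort A `cohort_data`.
#' @param score Standardized score from [compute_prs].
#' @return A list of class `prs_association`: `cohort_id`, `threshold`,
#'   `n_snps`, `n`, `beta_per_sd`, `se`, `p`, `or_per_sd`, `ci_low`,
#'   `ci_high`, `delta_r2_nagelkerke`.
#' @export
associate_prs <- function(cohort, score) {
  stopifnot(inherits(cohort, "cohort_data"))
  y <- cohort$phenotype
  if (length(unique(y)) < 2) {
    stop("phenotype has a single class; association is undefined", call. = FALSE)
  }
  dat <- data.frame(y = y, score = as.numeric(score))
  pc_names <- character(0)
  if (ncol(cohort$pcs) > 0) {
    pc_names <- paste0("PC", seq_len(ncol(cohort$pcs)))
    dat[pc_names] <- cohort$pcs
  }
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  full <- stats::glm(y ~ ., data = dat, family = stats::binomial(), control = ctrl)
  if (!full$converged) {
    stop(sprintf("logistic fit did not converge in %d iterations (cohort %s)",
                 ctrl$maxit, cohort$cohort_id), call. = FALSE)
  }
  fit <- stats::fitted(full)
  if (any(fit < 1e-10 | fit > 1 - 1e-10)) {
    warning(sprintf("fitted probabilities numerically 0/1 in cohort %s; possible separation",
                    cohort$cohort_id), call. = FALSE)
  }
  null <- stats::glm(y ~ . - score, data = dat, family = stats::binomial(),
                     control = ctrl)
  co <- summary(full)$coefficients
  b <- co["score", "Estimate"]
  se <- co["score", "Std. Error"]
  structure(list(
    cohort_id = cohort$cohort_id,
    threshold = attr(score, "threshold") %||% NA_real_,
    n_snps = attr(score, "n_snps") %||% NA_integer_,
    n = length(y),
    beta_per_sd = b, se = se,
    p = 2 * pnorm(-abs(b / se)),
    or_per_sd = exp(b),
    ci_low = exp(b - .z975 * se),
    ci_high = exp(b + .z975 * se),
    delta_r2_nagelkerke = nagelkerke_delta_r2(
      as.numeric(stats::logLik(null)), as.numeric(stats::logLik(full)), length(y))
  ), class = "prs_association")
}

#' @export
print.prs_association <- function(x, ...) {
  cat(sprintf("PRS association%s: OR/SD %.3f (95%% CI %.3f-%.3f), p = %.3g, dR2 = %.4g\n",
              if (is.na(x$cohort_id)) "" else paste0(" [", x$cohort_id, "]"),
              x$or_per_sd, x$ci_low, x$ci_high, x$p, x$delta_r2_nagelkerke))
  invisible(x)
}

#' Nagelkerke (max-rescaled Cox-Snell) pseudo-R-squared increment
#'
#' \deqn{R^2_{CS} = 1 - e^{2(\ell_0 - \ell_1)/n}, \qquad
#'       R^2_N = R^2_{CS} / (1 - e^{2\ell_0 / n})}
#' where \eqn{\ell_0} and \eqn{\ell_1} are the log-likelihoods of the nested
#' null and full models. With the covariates-only model as the null, this is
#' the variance-explained increment attributable to the PRS.
#'
#' @param ll_null Log-likelihood of the null model.
#' @param ll_full Log-likelihood of the full model (must be >= `ll_null` up
#'   to numerical tolerance).
#' @param n Number of observations.
#' @return The rescaled pseudo-R-squared, in \[0, 1).
#' @export
nagelkerke_delta_r2 <- function(ll_null, ll_full, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (ll_full < ll_null - 1e-8 * max(1, abs(ll_null))) {
    stop("ll_full < ll_null: models are not nested as assumed", call. = FALSE)
  }
  r2_cs <- 1 - exp(2 * (ll_null - ll_full) / n)
  max(0, r2_cs / (1 - exp(2 * ll_null / n)))
}

#' Fixed-effects inverse-variance-weighted meta-analysis of PRS associations
#'
#' Pools per-cohort log-OR estimates with weights \eqn{w_i = se_i^{-2}}:
#' pooled \eqn{b = \sum w_i b_i / \sum w_i}, pooled
#' \eqn{se = (\sum w_i)^{-1/2}}, Wald p, exponentiated OR and 95% CI.
#'
#' @param results List of `prs_association` objects (one per cohort).
#' @return A pooled `prs_association` with `cohort_id = "pooled"` and
#'   `n_cohorts` attached; `delta_r2_nagelkerke` is the
#'   inverse-variance-weighted mean of the per-cohort increments (reported,
#'   not pooled by likelihood).
#' @export
meta_analyze <- function(results) {
  if (length(results) == 0) stop("no cohort results to meta-analyze", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "prs_association")))
  b <- vapply(results, `[[`, numeric(1), "beta_per_sd")
  se <- vapply(results, `[[`, numeric(1), "se")
  w <- se^-2
  pb <- sum(w * b) / sum(w)
  pse <- sqrt(1 / sum(w))
  dr2 <- vapply(results, `[[`, numeric(1), "delta_r2_nagelkerke")
  structure(list(
    cohort_id = "pooled",
    threshold = results[[1]]$threshold,
    n_snps = results[[1]]$n_snps,
    n = sum(vapply(results, `[[`, numeric(1), "n")),
    n_cohorts = length(results),
    beta_per_sd = pb, se = pse,
    p = 2 * pnorm(-abs(pb / pse)),
    or_per_sd = exp(pb),
    ci_low = exp(pb - .z975 * pse),
    ci_high = exp(pb + .z975 * pse),
    delta_r2_nagelkerke = sum(w * dr2) / sum(w)
  ), class = "prs_association")
}

#' PRS threshold scan across cohorts with meta-analysis
#'
#' Runs [compute_prs] and [associate_prs] in every cohort at each exposure
#' p-value threshold and pools cohorts by fixed-effects meta-analysis.
#'
#' @param cohorts List of `cohort_data`.
#' @param thresholds Exposure p-value thresholds
#'   (default `c(1e-4, 0.001, 0.01, 0.05, 0.1)`).
#' @return A tibble with one row per threshold: `threshold`, `n_snps`,
#'   `n_cohorts`, `or_per_sd`, `ci_low`, `ci_high`, `p`, `delta_r2`.
#' @export
prs_threshold_scan <- function(cohorts,
                               thresholds = c(1e-4, 0.001, 0.01, 0.05, 0.1)) {
  rows <- lapply(thresholds, function(th) {
    fits <- lapply(cohorts, function(co) associate_prs(co, compute_prs(co, th)))
    pooled <- meta_analyze(fits)
    tibble::tibble(threshold = th, n_snps = pooled$n_snps,
                   n_cohorts = pooled$n_cohorts, or_per_sd = pooled$or_per_sd,
                   ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                   p = pooled$p, delta_r2 = pooled$delta_r2_nagelkerke)
  })
  dplyr::bind_rows(rows)
}
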