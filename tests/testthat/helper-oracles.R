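# Independent oracles and fixture builders shared across the suite.

# Weighted least-squares regression of beta on omega through the origin with
# weights se_beta^-2, via stats::lm. The fixed-effect slope SE is the lm SE
# divided by the residual standard error (lm rescales by sigma; the
# summary-statistics estimator assumes unit residual variance). The weighted
# residual sum of squares (lm deviance) is the heterogeneity Q.
wls_origin_oracle <- function(omega, beta, se_beta) {
  if (length(omega) == 1) {
    # single-SNP ratio estimate (delta method); lm has no residual df here
    return(list(alpha = beta / omega, se_alpha = abs(se_beta / omega), q = 0))
  }
  fit <- lm(beta ~ 0 + omega, weights = se_beta^-2)
  sm <- summary(fit)
  list(alpha = unname(coef(fit)[1]),
       se_alpha = unname(sm$coefficients[1, 2] / sm$sigma),
       q = deviance(fit))
}

# Direct maximum-likelihood logistic fit by Newton iterations on the
# log-likelihood, independent of stats::glm.
logistic_ml_oracle <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y - mu)
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- unname(sqrt(diag(solve(H))))
  list(coef = as.vector(beta), se = se)
}

# A small deterministic instrument/outcome fixture with matched alleles.
toy_tables <- function(m = 5, seed = 42) {
  set.seed(seed)
  rsid <- sprintf("rs%03d", seq_len(m))
  ea <- rep(c("A", "C"), length.out = m)
  oa <- rep(c("G", "T"), length.out = m)
  instrument <- tibble::tibble(
    rsid = rsid, chrom = "1", pos = seq_len(m) * 1000,
    effect_allele = ea, other_allele = oa,
    omega = runif(m, 0.02, 0.2), omega_se = runif(m, 0.005, 0.02),
    eaf = runif(m, 0.1, 0.5), locus = paste0("L", seq_len(m)))
  outcome <- tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    beta = rnorm(m, 0, 0.05), se_beta = runif(m, 0.01, 0.05),
    n_total = 1000L, n_cases = 400L, n_controls = 600L)
  list(instrument = instrument, outcome = outcome)
}

# Flip effect/other alleles and the sign of beta for every outcome row.
flip_outcome <- function(outcome) {
  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped
}
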