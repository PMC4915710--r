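test_that("PRS scoring sums weighted dosages, standardizes within cohort, and
           counts threshold membership correctly", {
  # hand-checkable raw score: omega (0.1, 0.3), dosages (2, 1) -> 0.5
  dos <- matrix(c(2, 0, 1, 2), nrow = 2,
                dimnames = list(NULL, c("rs1", "rs2")))
  meta <- tibble::tibble(rsid = c("rs1", "rs2"), effect_allele = "A",
                         omega = c(0.1, 0.3), exposure_p = c(1e-6, 1e-6))
  co <- cohort_data("c1", dos, c(1, 0), matrix(numeric(0), 2, 0), meta)
  raw <- as.vector(dos %*% meta$omega)
  expect_equal(raw[1], 0.5)
  sc <- compute_prs(co, 0.05)
  expect_equal(sc, (raw - mean(raw)) / sd(raw), ignore_attr = TRUE)
  expect_equal(attr(sc, "n_snps"), 2)

  # zero SNPs passing and zero-variance scores are errors
  expect_error(compute_prs(co, 1e-10), "threshold")
  meta0 <- meta; meta0$omega <- c(0, 0)
  co0 <- cohort_data("c1", dos, c(1, 0), matrix(numeric(0), 2, 0), meta0)
  expect_error(compute_prs(co0, 0.05), "degenerate")

  # threshold scan: n_snps matches brute-force filtering, non-decreasing
  co2 <- simulate_cohort(n_individuals = 300, m_snps = 20, seed = 5,
                         n_exposure = 500)  # small n: spread-out p-values
  ths <- c(1e-4, 0.001, 0.01, 0.05, 0.1)
  counts <- vapply(ths, function(t) {
    if (sum(co2$snp_meta$exposure_p <= t) == 0) 0L else
      attr(compute_prs(co2, t), "n_snps")
  }, integer(1))
  expect_equal(counts[counts > 0],
               vapply(ths, function(t) sum(co2$snp_meta$exposure_p <= t),
                      integer(1))[counts > 0])
  expect_true(all(diff(counts) >= 0))
})

test_that("standardization invariant holds on simulated cohorts", {
  for (seed in 1:5) {
    co <- simulate_cohort(n_individuals = 400, seed = seed, alpha_true = -0.1)
    sc <- compute_prs(co, 0.1)
    expect_lt(abs(mean(sc)), 1e-10)
    expect_lt(abs(sd(sc) - 1), 1e-10)
  }
})

test_that("logistic association matches an independent Newton ML fit", {
  co <- simulate_cohort(n_individuals = 200, seed = 17, alpha_true = -0.3,
                        n_pcs = 3)
  sc <- compute_prs(co, 0.1)
  fit <- associate_prs(co, sc)
  X <- cbind(1, as.numeric(sc), co$pcs)
  o <- logistic_ml_oracle(X, co$phenotype)
  expect_equal(fit$beta_per_sd, o$coef[2], tolerance = 1e-6)
  expect_equal(fit$se, o$se[2], tolerance = 1e-6)
  expect_equal(fit$or_per_sd, exp(fit$beta_per_sd))

  # single-class phenotype is rejected
  co1 <- co; co1$phenotype <- rep(1L, length(co$phenotype))
  expect_error(associate_prs(co1, sc), "single class")
})

test_that("Nagelkerke increment follows the closed form and its monotonicity", {
  expect_equal(nagelkerke_delta_r2(-5, -5, 20), 0)
  # hand case: n = 10, ll_null = 10 ln 0.5, ll_full = -5
  ll0 <- 10 * log(0.5)
  r2cs <- 1 - exp(2 * (ll0 - (-5)) / 10)
  expect_equal(nagelkerke_delta_r2(ll0, -5, 10), r2cs / (1 - exp(2 * ll0 / 10)))
  # strictly increasing in ll_full
  vals <- vapply(c(-6.5, -6, -5.5, -5), nagelkerke_delta_r2,
                 numeric(1), ll_null = ll0, n = 10)
  expect_true(all(diff(vals) > 0))
  expect_error(nagelkerke_delta_r2(-4, -5, 10), "nested")
})

test_that("fixed-effects meta-analysis obeys IVW arithmetic and matches an
           independent oracle", {
  co <- simulate_cohort(n_individuals = 400, seed = 23, alpha_true = -0.2)
  a <- associate_prs(co, compute_prs(co, 0.1))

  # single cohort: pooled result equals the input
  m1 <- meta_analyze(list(a))
  expect_equal(m1$beta_per_sd, a$beta_per_sd)
  expect_equal(m1$se, a$se)

  # k identical cohorts: same point estimate, se / sqrt(k)
  m4 <- meta_analyze(list(a, a, a, a))
  expect_equal(m4$beta_per_sd, a$beta_per_sd, tolerance = 1e-12)
  expect_equal(m4$se, a$se / 2, tolerance = 1e-12)

  # distinct cohorts match metafor's fixed-effect fit
  fits <- lapply(1:3, function(s) {
    cs <- simulate_cohort(n_individuals = 300, seed = 100 + s, alpha_true = -0.2)
    associate_prs(cs, compute_prs(cs, 0.1))
  })
  pooled <- meta_analyze(fits)
  rma <- metafor::rma(yi = vapply(fits, `[[`, numeric(1), "beta_per_sd"),
                      sei = vapply(fits, `[[`, numeric(1), "se"),
                      method = "FE")
  expect_equal(pooled$beta_per_sd, as.numeric(rma$beta), tolerance = 1e-12)
  expect_equal(pooled$se, rma$se, tolerance = 1e-12)
  expect_error(meta_analyze(list()), "no cohort")
})

test_that("a split cohort meta-analyzed approximates the unsplit fit", {
  co <- simulate_cohort(n_individuals = 1200, seed = 57, alpha_true = -0.25,
                        n_pcs = 0)
  full <- associate_prs(co, compute_prs(co, 0.1))
  idx <- seq_len(600)
  halves <- lapply(list(idx, -idx), function(ii) {
    cohort_data("half", co$dosages[ii, , drop = FALSE], co$phenotype[ii],
                co$pcs[ii, , drop = FALSE], co$snp_meta)
  })
  pooled <- meta_analyze(lapply(halves, function(h)
    associate_prs(h, compute_prs(h, 0.1))))
  expect_lt(abs(pooled$beta_per_sd - full$beta_per_sd), 3 * pooled$se)
})
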