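make_harmonized <- function(d, seed = 5) {
  m <- nrow(d)
  inst <- tibble::tibble(rsid = sprintf("rs%03d", seq_len(m)),
                         effect_allele = "A", other_allele = "G",
                         omega = d$omega, omega_se = 0.005,
                         locus = paste0("L", seq_len(m)))
  out <- tibble::tibble(rsid = inst$rsid, effect_allele = "A",
                        other_allele = "G", beta = d$beta, se_beta = d$se_beta)
  harmonize(inst, out)
}

test_that("Q is the weighted residual sum of squares about the fitted slope", {
  # exact proportionality: zero residuals, p-het = 1
  h <- make_harmonized(data.frame(omega = c(0.1, 0.2, 0.3),
                                  beta = c(0.02, 0.04, 0.06), se_beta = 0.05))
  het <- q_statistic(h)
  expect_equal(het$q, 0, tolerance = 1e-20)
  expect_equal(het$p_het, 1)
  expect_equal(het$df, 2)

  # random instances: Q equals the regression oracle's weighted RSS and the
  # contributions sum to Q
  set.seed(11)
  for (i in 1:20) {
    m <- sample(3:15, 1)
    d <- data.frame(omega = runif(m, 0.02, 0.2), beta = rnorm(m, 0, 0.1),
                    se_beta = runif(m, 0.01, 0.1))
    h <- make_harmonized(d)
    het <- q_statistic(h)
    o <- wls_origin_oracle(d$omega, d$beta, d$se_beta)
    expect_equal(het$q, o$q, tolerance = 1e-10)
    expect_equal(sum(het$per_snp_contrib$contribution), het$q, tolerance = 1e-12)
  }

  expect_error(q_statistic(data.frame(omega = 0.1, beta = 0.02, se_beta = 0.05)),
               "at least 2")
})

test_that("Q is invariant to SNP permutation and joint allele reorientation", {
  set.seed(21)
  tt <- toy_tables(m = 10)
  h <- harmonize(tt$instrument, tt$outcome)
  q0 <- q_statistic(h)$q
  hp <- h
  perm <- sample(nrow(hp$pairs))
  hp$pairs <- hp$pairs[perm, ]
  expect_equal(q_statistic(hp)$q, q0, tolerance = 1e-12)
  hf <- harmonize(tt$instrument, flip_outcome(tt$outcome))
  expect_equal(q_statistic(hf)$q, q0, tolerance = 1e-12)
})

test_that("stepwise pruning removes a planted outlier first and stops when
           heterogeneity clears", {
  # homogeneous data: zero steps
  h0 <- make_harmonized(data.frame(omega = seq(0.05, 0.2, length.out = 6),
                                   beta = 0.3 * seq(0.05, 0.2, length.out = 6),
                                   se_beta = 0.05))
  tr0 <- prune_heterogeneity(h0)
  expect_equal(nrow(tr0$steps), 0)
  expect_equal(tr0$final_m, 6)

  # one SNP with a large direct effect dominates the contributions and is
  # removed at step 1; brute-force ranking confirms
  set.seed(31)
  m <- 12
  omega <- runif(m, 0.05, 0.2)
  beta <- 0.2 * omega + rnorm(m, 0, 0.01)
  beta[7] <- beta[7] + 0.5
  d <- data.frame(omega = omega, beta = beta, se_beta = 0.01)
  h <- make_harmonized(d)
  het <- q_statistic(h)
  expect_equal(which.max(het$per_snp_contrib$contribution), 7)
  tr <- prune_heterogeneity(h)
  expect_equal(tr$steps$removed_rsid[1], "rs007")
  expect_gte(tr$final_q$p_het, 0.05)
  # every recorded step was taken under significant heterogeneity
  expect_true(all(tr$steps$p_het_before < 0.05))

  # determinism: identical input gives an identical trace
  tr2 <- prune_heterogeneity(h)
  expect_identical(tr$steps, tr2$steps)
  expect_identical(tr$final_estimate$alpha, tr2$final_estimate$alpha)

  # floor: two wildly inconsistent SNPs cannot be pruned below 2
  h2 <- make_harmonized(data.frame(omega = c(0.1, 0.1),
                                   beta = c(0.5, -0.5), se_beta = 0.01))
  expect_warning(trf <- prune_heterogeneity(h2), "floor")
  expect_true(trf$floor_reached)
  expect_equal(trf$final_m, 2)
})

test_that("leave-one-out re-estimates each subset exactly", {
  set.seed(41)
  m <- 8
  d <- data.frame(omega = runif(m, 0.05, 0.2), beta = rnorm(m, 0, 0.05),
                  se_beta = runif(m, 0.01, 0.05))
  h <- make_harmonized(d)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), m)
  expect_true(all(loo$m_used == m - 1))
  for (i in seq_len(m)) {
    direct <- estimate_causal_effect(d[-i, ])
    expect_equal(loo$alpha[loo$excluded_rsid == sprintf("rs%03d", i)],
                 direct$alpha, tolerance = 1e-12)
  }

  # exact proportionality: all leave-one-out estimates identical
  hp <- make_harmonized(data.frame(omega = seq(0.05, 0.2, length.out = 5),
                                   beta = 0.4 * seq(0.05, 0.2, length.out = 5),
                                   se_beta = 0.03))
  expect_equal(diff(range(leave_one_out(hp)$alpha)), 0, tolerance = 1e-12)
})
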