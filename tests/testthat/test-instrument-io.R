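test_that("weight files round-trip through the TSV schema and are validated", {
  tt <- toy_tables()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(tt$instrument, path)
  back <- read_weights(path)
  expect_equal(back$rsid, tt$instrument$rsid)
  expect_equal(back$omega, tt$instrument$omega, tolerance = 1e-12)

  # header-only file: empty tibble plus a warning
  empty <- tt$instrument[0, ]
  readr::write_delim(empty, path, delim = "\t")
  expect_warning(out <- read_weights(path), "no rows")
  expect_equal(nrow(out), 0)

  # schema error names the missing column
  broken <- tt$instrument[, setdiff(names(tt$instrument), "omega")]
  readr::write_delim(broken, path, delim = "\t")
  expect_error(read_weights(path), "omega")

  # duplicated rsid names the duplicate
  dup <- rbind(tt$instrument, tt$instrument[1, ])
  expect_error(validate_weights(dup), tt$instrument$rsid[1])

  # non-numeric omega reported with its row
  bad <- tt$instrument
  bad$omega <- as.character(bad$omega)
  bad$omega[3] <- "x"
  expect_error(validate_weights(bad), "row 3")
})

test_that("outcome tables enforce se_beta > 0 and allow missing case counts", {
  tt <- toy_tables()
  bad <- tt$outcome
  bad$se_beta[2] <- 0
  expect_error(validate_outcome_stats(bad), "se_beta")

  quant <- tt$outcome
  quant$n_cases <- NA_integer_
  quant$n_controls <- NA_integer_
  expect_silent(validate_outcome_stats(quant))

  off <- tt$outcome
  off$n_total[1] <- off$n_total[1] + 1L
  expect_error(validate_outcome_stats(off), "n_cases")
})

test_that("harmonization matches rsids, flips swapped alleles, drops mismatches", {
  tt <- toy_tables(m = 6)
  out <- tt$outcome
  # row 2: swapped orientation; row 4: alleles from another variant
  out$effect_allele[2] <- tt$outcome$other_allele[2]
  out$other_allele[2] <- tt$outcome$effect_allele[2]
  out$beta[2] <- 0.1
  out$effect_allele[4] <- "T"; out$other_allele[4] <- "A"
  h <- harmonize(tt$instrument, out)
  expect_s3_class(h, "harmonized_instrument")
  expect_equal(h$m_used, 5)
  expect_equal(h$pairs$beta[h$pairs$rsid == "rs002"], -0.1)
  expect_equal(h$dropped$reason, "allele_mismatch")
  # bookkeeping invariant
  expect_equal(h$m_used + nrow(h$dropped), nrow(tt$instrument))
  audit <- harmonization_audit(h)
  expect_equal(nrow(audit), nrow(tt$instrument))
})

test_that("SNPs absent from the outcome data are dropped; the published 18-SNP
           score loses exactly its three absent members against the
           schizophrenia-style table", {
  snps <- grs_gwas_snps()
  expect_equal(nrow(snps), 18)
  # synthetic weights: membership is published, weight values are not
  set.seed(1)
  instrument <- tibble::tibble(
    rsid = snps$rsid, chrom = snps$chrom, pos = snps$pos,
    effect_allele = "A", other_allele = "G",
    omega = runif(18, 0.02, 0.2), omega_se = 0.005, locus = snps$locus)
  present <- snps$rsid[snps$in_scz_data]
  outcome <- tibble::tibble(
    rsid = present, effect_allele = "A", other_allele = "G",
    beta = rnorm(length(present), 0, 0.02), se_beta = 0.02)
  h <- harmonize(instrument, outcome, grs_label = "GRS_GWAS")
  expect_equal(h$m_used, 15)
  expect_setequal(h$dropped$rsid, c("rs9987289", "rs1183910", "rs4420638"))
  expect_true(all(h$dropped$reason == "missing"))
})

test_that("proxy resolution takes max r2 above the strict 0.9 threshold,
           breaking ties by distance then rsid", {
  tt <- toy_tables(m = 3)
  out <- tt$outcome[-1, ]  # rs001 missing
  proxy_rows <- tibble::tibble(
    rsid = c("rsP1", "rsP2", "rsP3"),
    effect_allele = "A", other_allele = "G",
    beta = c(0.11, 0.22, 0.33), se_beta = 0.02,
    n_total = 1000L, n_cases = 400L, n_controls = 600L)
  out <- dplyr::bind_rows(out, proxy_rows)
  proxies <- tibble::tibble(
    original_rsid = "rs001",
    proxy_rsid = c("rsP1", "rsP2", "rsP3"),
    r2 = c(0.95, 0.85, 0.95),
    distance_bp = c(500, 100, 200))
  h <- harmonize(tt$instrument, out, proxies = proxies)
  expect_equal(h$m_used, 3)
  # both 0.95 candidates tie on r2; rsP3 is nearer
  expect_equal(h$proxies_used$proxy_rsid, "rsP3")
  expect_equal(h$pairs$beta[h$pairs$rsid == "rs001"], 0.33)

  # all candidates below threshold: SNP dropped (r2 = 0.9 is not eligible)
  weak <- proxies
  weak$r2 <- c(0.9, 0.85, 0.8)
  h2 <- harmonize(tt$instrument, out, proxies = weak)
  expect_equal(h2$m_used, 2)
  expect_equal(h2$dropped$reason, "missing")

  # no proxies at all: drop is the default behaviour
  h3 <- harmonize(tt$instrument, out)
  expect_equal(h3$m_used, 2)
})

test_that("palindromic SNPs are flagged by default and dropped in strict mode", {
  tt <- toy_tables(m = 3)
  tt$instrument$effect_allele[1] <- "A"; tt$instrument$other_allele[1] <- "T"
  tt$outcome$effect_allele[1] <- "A"; tt$outcome$other_allele[1] <- "T"
  h <- harmonize(tt$instrument, tt$outcome)
  expect_true(h$pairs$palindromic[h$pairs$rsid == "rs001"])
  h2 <- harmonize(tt$instrument, tt$outcome, drop_palindromic = TRUE)
  expect_equal(h2$dropped$reason, "palindromic")
  expect_equal(h2$m_used, 2)
})

test_that("harmonization is idempotent and invariant to joint reorientation", {
  tt <- toy_tables(m = 8, seed = 9)
  h <- harmonize(tt$instrument, tt$outcome)

  # orientation invariance: flipping alleles + beta sign of every outcome row
  h_flip <- harmonize(tt$instrument, flip_outcome(tt$outcome))
  expect_equal(h_flip$pairs, h$pairs)

  # idempotence: re-harmonizing the aligned pairs changes nothing
  out2 <- tibble::tibble(
    rsid = h$pairs$rsid, effect_allele = h$pairs$effect_allele,
    other_allele = h$pairs$other_allele, beta = h$pairs$beta,
    se_beta = h$pairs$se_beta)
  h2 <- harmonize(h$pairs, out2)
  expect_equal(h2$pairs$beta, h$pairs$beta)
  expect_equal(h2$m_used, h$m_used)

  # empty result is an error, not an empty object
  alien <- tt$outcome
  alien$rsid <- paste0("x", alien$rsid)
  expect_error(harmonize(tt$instrument, alien), "dropped all")
})
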