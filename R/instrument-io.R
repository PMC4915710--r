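#' @importFrom rlang .data
#' @importFrom stats pchisq pnorm qnorm sd var setNames
#' @importFrom utils head
NULL

# Required columns for the two tabular schemas. `eaf` and `locus` are optional
# in weight files; case/control counts are optional for quantitative outcomes.
.weights_required <- c("rsid", "effect_allele", "other_allele", "omega", "omega_se")
.weights_optional <- c("chrom", "pos", "eaf", "locus")
.outcome_required <- c("rsid", "effect_allele", "other_allele", "beta", "se_beta")
.outcome_optional <- c("n_total", "n_cases", "n_controls")
.proxy_required   <- c("original_rsid", "proxy_rsid", "r2", "distance_bp")

.norm_allele <- function(x) toupper(trimws(as.character(x)))

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  ok <- a1 %in% names(.complement) & a2 %in% names(.complement)
  ok & unname(.complement[a1]) == a2
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.check_numeric <- function(df, cols, what) {
  for (col in intersect(cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("%s table: non-numeric value in column '%s' at row %d ('%s')",
                     what, col, bad[1], v[bad[1]]), call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Validate an instrument weight table
#'
#' Checks the schema and invariants of a table of exposure-associated variants:
#' one row per SNP with its per-allele weight on the (ln-scale) exposure.
#'
#' @param df A data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `omega`, `omega_se` (and optionally `chrom`, `pos`, `eaf`, `locus`).
#' @return The validated table as a tibble, with alleles upper-cased.
#' @export
validate_weights <- function(df) {
  .check_columns(df, .weights_required, "weights")
  df <- .check_numeric(df, c("omega", "omega_se", "eaf", "pos"), "weights")
  df <- tibble::as_tibble(df)
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- .norm_allele(df$effect_allele)
  df$other_allele <- .norm_allele(df$other_allele)
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup) > 0) {
    stop(sprintf("duplicated rsid in weights table: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(!is.na(df$omega_se) & df$omega_se <= 0)) {
    stop("weights table: omega_se must be > 0", call. = FALSE)
  }
  same <- df$effect_allele == df$other_allele
  if (any(same)) {
    stop(sprintf("weights table: effect and other allele identical for %s",
                 paste(df$rsid[same], collapse = ", ")), call. = FALSE)
  }
  if ("eaf" %in% names(df) && any(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))) {
    stop("weights table: eaf must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Validate an outcome summary-statistics table
#'
#' @param df A data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se_beta` (and optionally `n_total`, `n_cases`, `n_controls`).
#' @return The validated tibble.
#' @export
validate_outcome_stats <- function(df) {
  .check_columns(df, .outcome_required, "outcome")
  df <- .check_numeric(df, c("beta", "se_beta", "n_total", "n_cases", "n_controls"),
                       "outcome")
  df <- tibble::as_tibble(df)
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- .norm_allele(df$effect_allele)
  df$other_allele <- .norm_allele(df$other_allele)
  if (any(is.na(df$se_beta) | df$se_beta <= 0)) {
    bad <- which(is.na(df$se_beta) | df$se_beta <= 0)[1]
    stop(sprintf("outcome table: se_beta must be > 0 (row %d, rsid %s)",
                 bad, df$rsid[bad]), call. = FALSE)
  }
  if (all(c("n_total", "n_cases", "n_controls") %in% names(df))) {
    full <- !is.na(df$n_total) & !is.na(df$n_cases) & !is.na(df$n_controls)
    off <- full & (df$n_cases + df$n_controls != df$n_total)
    if (any(off)) {
      stop(sprintf("outcome table: n_cases + n_controls != n_total for %s",
                   paste(df$rsid[off], collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read an instrument weight table
#'
#' Reads a delimited text file of per-SNP exposure weights (tab-separated by
#' default, `.` for missing values) and validates it.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default tab).
#' @param na Strings treated as missing (default `"."` and empty).
#' @return A tibble of validated instrument SNPs, in file order.
#' @export
read_weights <- function(path, delim = "\t", na = c(".", "", "NA")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_delim(path, delim = delim, na = na, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("weights file '%s' contains a header but no rows", path),
            call. = FALSE)
    .check_columns(df, .weights_required, "weights")
    return(tibble::as_tibble(df))
  }
  validate_weights(df)
}

#' Read an outcome summary-statistics table
#'
#' @inheritParams read_weights
#' @param outcome_name Label attached to the table (attribute `outcome_name`).
#' @param outcome_type `"binary"` or `"quantitative"`; attached as attribute.
#' @return A tibble of validated per-SNP outcome associations.
#' @export
read_outcome_stats <- function(path, delim = "\t", na = c(".", "", "NA"),
                               outcome_name = NULL,
                               outcome_type = c("binary", "quantitative")) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_delim(path, delim = delim, na = na, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("outcome file '%s' contains a header but no rows", path),
            call. = FALSE)
    .check_columns(df, .outcome_required, "outcome")
    df <- tibble::as_tibble(df)
  } else {
    df <- validate_outcome_stats(df)
  }
  attr(df, "outcome_name") <- outcome_name %||% "outcome"
  attr(df, "outcome_type") <- outcome_type
  df
}

#' Read a proxy (LD surrogate) table
#'
#' @inheritParams read_weights
#' @return A tibble with columns `original_rsid`, `proxy_rsid`, `r2`,
#'   `distance_bp`.
#' @export
read_proxies <- function(path, delim = "\t", na = c(".", "", "NA")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- readr::read_delim(path, delim = delim, na = na, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  .check_columns(df, .proxy_required, "proxy")
  df <- .check_numeric(df, c("r2", "distance_bp"), "proxy")
  df <- tibble::as_tibble(df)
  if (any(df$r2 < 0 | df$r2 > 1)) stop("proxy table: r2 must lie in [0, 1]", call. = FALSE)
  if (any(df$distance_bp < 0)) stop("proxy table: distance_bp must be >= 0", call. = FALSE)
  df
}

#' Write instrument / outcome / proxy tables
#'
#' Writers emitting the same tab-separated schemas the readers consume, with
#' `.` for missing values.
#'
#' @param df Table to write.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_weights <- function(df, path, delim = "\t") {
  validate_weights(df)
  readr::write_delim(df, path, delim = delim, na = ".")
  invisible(path)
}

#' @rdname write_weights
#' @export
write_outcome_stats <- function(df, path, delim = "\t") {
  validate_outcome_stats(df)
  readr::write_delim(df, path, delim = delim, na = ".")
  invisible(path)
}

# Pick the best eligible proxy for one missing instrument SNP: highest r2
# (strictly above `r2_min`), ties by smallest distance, then rsid order.
.best_proxy <- function(rsid, proxies, available, r2_min) {
  cand <- proxies[proxies$original_rsid == rsid & proxies$proxy_rsid %in% available, ,
                  drop = FALSE]
  cand <- cand[cand$r2 > r2_min, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ord <- order(-cand$r2, cand$distance_bp, cand$proxy_rsid)
  cand[ord[1], , drop = FALSE]
}

#' Harmonize an instrument against outcome summary statistics
#'
#' Joins each instrument SNP to its outcome record, resolving missing SNPs via
#' LD proxies and aligning effect alleles. For each instrument SNP: a direct
#' rsid match is used when present; otherwise the eligible proxy with the
#' highest r-squared (strictly greater than `r2_min`; ties broken by smallest
#' distance, then by proxy rsid) is substituted; otherwise the SNP is dropped
#' with reason `"missing"`. When the outcome record's alleles are swapped
#' relative to the instrument, the outcome effect is sign-flipped and the
#' alleles reoriented; allele sets matching neither orientation drop the SNP
#' with reason `"allele_mismatch"`. Palindromic (A/T, C/G) SNPs are retained
#' and flagged unless `drop_palindromic = TRUE`. Matching is by nucleotide
#' identity only — no strand inference is attempted.
#'
#' Proxy records are assumed pre-oriented: the proxy's outcome effect is taken
#' as reported, on the allele tagging the instrument SNP's effect allele.
#'
#' @param instrument Validated instrument weight table (see [validate_weights]).
#' @param outcome Validated outcome table (see [validate_outcome_stats]).
#' @param proxies Optional proxy table (see [read_proxies]); `NULL` disables
#'   proxy search, so missing SNPs are simply dropped.
#' @param r2_min Proxy eligibility threshold; strict inequality (default 0.9).
#' @param drop_palindromic If `TRUE`, drop strand-ambiguous SNPs with reason
#'   `"palindromic"` instead of flagging them.
#' @param grs_label Label for the instrument (e.g. `"GRS_GWAS"`).
#' @param outcome_name,outcome_type Overrides for the outcome table attributes.
#' @return An object of class `harmonized_instrument`: a list with `pairs`
#'   (tibble of aligned per-SNP rows), `m_used`, `dropped` (tibble of rsid and
#'   reason), `proxies_used`, `outcome_name`, `outcome_type`, `grs_label`.
#' @export
harmonize <- function(instrument, outcome, proxies = NULL, r2_min = 0.9,
                      drop_palindromic = FALSE, grs_label = "custom",
                      outcome_name = NULL, outcome_type = NULL) {
  instrument <- validate_weights(instrument)
  if (nrow(instrument) == 0) stop("instrument table is empty", call. = FALSE)
  out_name <- outcome_name %||% attr(outcome, "outcome_name") %||% "outcome"
  out_type <- outcome_type %||% attr(outcome, "outcome_type") %||% "binary"
  outcome <- validate_outcome_stats(outcome)
  if (!is.null(proxies)) .check_columns(proxies, .proxy_required, "proxy")

  pairs <- list(); dropped <- list(); proxies_used <- list()
  for (i in seq_len(nrow(instrument))) {
    snp <- instrument[i, , drop = FALSE]
    hit <- outcome[outcome$rsid == snp$rsid, , drop = FALSE]
    proxy_rsid <- NA_character_
    if (nrow(hit) == 0 && !is.null(proxies)) {
      best <- .best_proxy(snp$rsid, proxies, outcome$rsid, r2_min)
      if (!is.null(best)) {
        hit <- outcome[outcome$rsid == best$proxy_rsid, , drop = FALSE]
        proxy_rsid <- best$proxy_rsid
        proxies_used[[length(proxies_used) + 1L]] <- tibble::as_tibble(best)
      }
    }
    if (nrow(hit) == 0) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(rsid = snp$rsid,
                                                        reason = "missing")
      next
    }
    hit <- hit[1, , drop = FALSE]
    beta <- hit$beta
    if (is.na(proxy_rsid)) {
      if (hit$effect_allele == snp$effect_allele &&
          hit$other_allele == snp$other_allele) {
        # aligned as-is
      } else if (hit$effect_allele == snp$other_allele &&
                 hit$other_allele == snp$effect_allele) {
        beta <- -beta
      } else {
        dropped[[length(dropped) + 1L]] <- tibble::tibble(rsid = snp$rsid,
                                                          reason = "allele_mismatch")
        next
      }
    }
    palin <- .is_palindromic(snp$effect_allele, snp$other_allele)
    if (palin && drop_palindromic) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(rsid = snp$rsid,
                                                        reason = "palindromic")
      next
    }
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      rsid = snp$rsid,
      effect_allele = snp$effect_allele,
      other_allele = snp$other_allele,
      omega = snp$omega,
      omega_se = snp$omega_se,
      beta = beta,
      se_beta = hit$se_beta,
      locus = if ("locus" %in% names(snp)) snp$locus else NA_character_,
      palindromic = palin,
      proxy_rsid = proxy_rsid
    )
  }

  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(rsid = character(), effect_allele = character(),
                   other_allele = character(), omega = double(),
                   omega_se = double(), beta = double(), se_beta = double(),
                   locus = character(), palindromic = logical(),
                   proxy_rsid = character())
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(rsid = character(), reason = character())
  if (nrow(pairs) == 0) {
    stop(sprintf("harmonization dropped all %d instrument SNPs for outcome '%s'",
                 nrow(instrument), out_name), call. = FALSE)
  }
  structure(list(
    pairs = pairs,
    m_used = nrow(pairs),
    dropped = dropped,
    proxies_used = if (length(proxies_used)) dplyr::bind_rows(proxies_used) else
      tibble::tibble(original_rsid = character(), proxy_rsid = character(),
                     r2 = double(), distance_bp = double()),
    outcome_name = out_name,
    outcome_type = out_type,
    grs_label = grs_label
  ), class = "harmonized_instrument")
}

#' @export
print.harmonized_instrument <- function(x, ...) {
  cat(sprintf("Harmonized instrument: %s vs %s (%s)\n", x$grs_label,
              x$outcome_name, x$outcome_type))
  cat(sprintf("  SNPs used: %d; dropped: %d; proxies: %d; palindromic flagged: %d\n",
              x$m_used, nrow(x$dropped), nrow(x$proxies_used),
              sum(x$pairs$palindromic)))
  invisible(x)
}

#' Harmonization audit table
#'
#' One row per input instrument SNP recording what happened to it
#' (`used`, `proxy`, or the drop reason).
#'
#' @param h A `harmonized_instrument`.
#' @return A tibble with columns `rsid`, `action`, `reason`.
#' @export
harmonization_audit <- function(h) {
  stopifnot(inherits(h, "harmonized_instrument"))
  used <- tibble::tibble(
    rsid = h$pairs$rsid,
    action = ifelse(is.na(h$pairs$proxy_rsid), "used", "proxy"),
    reason = ifelse(is.na(h$pairs$proxy_rsid), ".", h$pairs$proxy_rsid)
  )
  drop <- tibble::tibble(rsid = h$dropped$rsid, action = "dropped",
                         reason = h$dropped$reason)
  dplyr::bind_rows(used, drop)
}

#' @rdname harmonization_audit
#' @param path Output path for the tab-separated audit.
#' @export
write_harmonization_audit <- function(h, path) {
  readr::write_delim(harmonization_audit(h), path, delim = "\t", na = ".")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
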