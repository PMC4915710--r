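# Multi-outcome panel orchestration: per-(GRS, outcome) estimate, F, Q, a
# second pruning pass over heterogeneous analyses, and significance tiers.

#' Bonferroni-corrected significance threshold
#'
#' @param global_level Family-wise significance level (default 0.05).
#' @param n_tests Number of independent outcome sample sets tested.
#' @return `global_level / n_tests` (unrounded; reports present 4 decimals,
#'   so 0.05/32 prints as 0.0016).
#' @export
bonferroni_threshold <- function(global_level = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  global_level / n_tests
}

#' Classify a p-value into significance tiers
#'
#' Three tiers with inclusive boundaries: `p <= bonf` is `"significant"`,
#' `bonf < p <= nominal` is `"nominal"`, `p > nominal` is `"none"`.
#'
#' @param p Observed p-value(s) in \[0, 1\].
#' @param bonf Bonferroni-corrected threshold.
#' @param nominal Nominal threshold (default 0.05).
#' @return Character vector of tiers.
#' @export
classify_significance <- function(p, bonf, nominal = 0.05) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(p <= bonf, "significant", ifelse(p <= nominal, "nominal", "none"))
}

.panel_row <- function(h, e, het, f_value, bonf, nominal, pruned = FALSE,
                       n_removed = 0L, floor_reached = FALSE) {
  tibble::tibble(
    outcome = h$outcome_name, grs_label = h$grs_label, pruned = pruned,
    m_used = e$m_used, alpha = e$alpha, se_alpha = e$se_alpha,
    or_point = e$or_point, or_low = e$or_low, or_high = e$or_high,
    p_assoc = e$p_assoc,
    q = if (is.null(het)) NA_real_ else het$q,
    df = if (is.null(het)) NA_integer_ else het$df,
    p_het = if (is.null(het)) NA_real_ else het$p_het,
    f_value = f_value, bonferroni = bonf,
    tier = classify_significance(e$p_assoc, bonf, nominal),
    n_removed = n_removed, floor_reached = floor_reached)
}

#' Run a multi-outcome GRS-MR panel
#'
#' For every (GRS, outcome) pair: harmonize, estimate the causal effect,
#' attach the instrument-strength F, and test heterogeneity; then a second
#' pass re-runs every heterogeneous analysis (`p_het < prune_threshold`)
#' through stepwise pruning and appends the post-pruning estimates.
#' Per-analysis failures are recorded and skipped; the run continues.
#'
#' @param instruments Named list of instrument weight tables; names are GRS
#'   labels.
#' @param outcomes Named list of outcome summary-statistics tables (each
#'   carrying `outcome_name`/`outcome_type` attributes, or plain tibbles —
#'   the list names are used as outcome labels).
#' @param outcome_meta Optional tibble with columns `outcome`, `n_total` (and
#'   optionally `outcome_type`) used for F-statistics.
#' @param r2 Named numeric vector of exposure variance explained per GRS
#'   (e.g. `c(GRS_CRP = 0.02, GRS_GWAS = 0.05)`).
#' @param proxies Optional proxy table shared across outcomes.
#' @param global_level Family-wise level for the Bonferroni threshold
#'   (default 0.05); the denominator is the number of outcome sets.
#' @param nominal Nominal significance level (default 0.05).
#' @param prune_threshold Heterogeneity p-value below which the pruning pass
#'   is applied (default 0.05).
#' @param drop_palindromic Passed to [harmonize].
#' @return A list of class `panel_report`: `report` (tibble, one row per
#'   analysis plus one per pruned analysis), `failures` (tibble), `bonferroni`.
#' @export
run_panel <- function(instruments, outcomes, outcome_meta = NULL,
                      r2 = NULL, proxies = NULL, global_level = 0.05,
                      nominal = 0.05, prune_threshold = 0.05,
                      drop_palindromic = FALSE) {
  if (length(instruments) == 0 || length(outcomes) == 0) {
    stop("panel needs at least one instrument and one outcome", call. = FALSE)
  }
  if (is.null(names(instruments)) || is.null(names(outcomes))) {
    stop("instruments and outcomes must be named lists", call. = FALSE)
  }
  bonf <- bonferroni_threshold(global_level, length(outcomes))
  rows <- list(); failures <- list()
  for (grs in names(instruments)) {
    for (out in names(outcomes)) {
      res <- tryCatch({
        otab <- outcomes[[out]]
        h <- harmonize(instruments[[grs]], otab, proxies = proxies,
                       drop_palindromic = drop_palindromic,
                       grs_label = grs, outcome_name = out)
        e <- estimate_causal_effect(h)
        het <- if (h$m_used >= 2) q_statistic(h, e) else NULL
        f_value <- NA_real_
        if (!is.null(outcome_meta) && !is.null(r2) && grs %in% names(r2)) {
          n <- outcome_meta$n_total[match(out, outcome_meta$outcome)]
          if (length(n) == 1 && !is.na(n)) f_value <- f_statistic(r2[[grs]], n, 1)
        }
        row <- .panel_row(h, e, het, f_value, bonf, nominal)
        if (!is.null(het) && het$p_het < prune_threshold) {
          tr <- suppressWarnings(prune_heterogeneity(h, p_threshold = prune_threshold))
          row <- dplyr::bind_rows(row, .panel_row(
            tr$final_instrument, tr$final_estimate, tr$final_q, f_value, bonf,
            nominal, pruned = TRUE, n_removed = nrow(tr$steps),
            floor_reached = tr$floor_reached))
        }
        row
      }, error = function(err) {
        failures[[length(failures) + 1L]] <<- tibble::tibble(
          grs_label = grs, outcome = out, error = conditionMessage(err))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  structure(list(
    report = if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(),
    failures = if (length(failures)) dplyr::bind_rows(failures) else
      tibble::tibble(grs_label = character(), outcome = character(),
                     error = character()),
    bonferroni = bonf
  ), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Panel report: %d analysis rows (%d pruned), %d failure(s); Bonferroni %.4f\n",
              nrow(x$report), sum(x$report$pruned), nrow(x$failures),
              x$bonferroni))
  invisible(x)
}

#' Write a panel report as a tab-separated table
#'
#' @param panel A `panel_report`.
#' @param path Output path.
#' @export
write_panel_report <- function(panel, path) {
  stopifnot(inherits(panel, "panel_report"))
  readr::write_delim(panel$report, path, delim = "\t", na = ".")
  invisible(path)
}
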