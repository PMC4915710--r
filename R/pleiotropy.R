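# Heterogeneity of per-SNP causal ratios: Cochran-style Q about the fitted
# GRS slope, stepwise pruning of the largest contributor, and leave-one-out.

#' Cochran Q heterogeneity of per-SNP effects about the fitted slope
#'
#' The per-SNP contribution is the squared weighted residual
#' \eqn{se_{\beta j}^{-2} (\beta_j - \alpha\,\omega_j)^2}; their sum is
#' referred to a chi-square distribution with \eqn{M - 1} degrees of freedom
#' (one parameter, the slope, is estimated). Significant heterogeneity
#' indicates that some SNPs affect the outcome through pathways other than
#' the exposure (pleiotropy), violating the exclusion assumption.
#'
#' @param h A `harmonized_instrument` or data frame with `omega`, `beta`,
#'   `se_beta` (needs at least 2 SNPs).
#' @param e Optional `causal_estimate` fitted on `h`; refitted if omitted.
#' @return A list of class `heterogeneity_result`: `q`, `df`, `p_het`,
#'   `per_snp_contrib` (tibble of rsid and contribution).
#' @export
q_statistic <- function(h, e = NULL) {
  pairs <- .pairs_of(h)
  if (nrow(pairs) < 2) {
    stop("heterogeneity requires at least 2 SNPs", call. = FALSE)
  }
  if (is.null(e)) e <- estimate_causal_effect(h)
  contrib <- pairs$se_beta^-2 * (pairs$beta - e$alpha * pairs$omega)^2
  q <- sum(contrib)
  df <- nrow(pairs) - 1L
  structure(list(
    q = q, df = df, p_het = pchisq(q, df, lower.tail = FALSE),
    per_snp_contrib = tibble::tibble(
      rsid = if ("rsid" %in% names(pairs)) pairs$rsid else
        paste0("snp_", seq_len(nrow(pairs))),
      contribution = contrib
    )
  ), class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Q = %.3f on %d df, p-het = %.3g\n", x$q, x$df, x$p_het))
  invisible(x)
}

.drop_snp <- function(h, rsid) {
  keep <- h$pairs$rsid != rsid
  h$pairs <- h$pairs[keep, , drop = FALSE]
  h$m_used <- nrow(h$pairs)
  h
}

#' Stepwise pleiotropy pruning by heterogeneity
#'
#' Repeatedly fits the causal estimate, computes Q, and — while the
#' heterogeneity p-value is below `p_threshold` — removes the single SNP with
#' the largest Q contribution (ties broken by rsid order), refitting after
#' every removal, until heterogeneity is no longer significant. Never prunes
#' below `floor` SNPs (at least 2 are needed for Q); if the floor is reached
#' while still heterogeneous, the trace is returned with `floor_reached = TRUE`
#' and a warning.
#'
#' @param h A `harmonized_instrument` (at least 2 SNPs).
#' @param p_threshold Stopping threshold on the heterogeneity p-value
#'   (default 0.05).
#' @param floor Minimum number of SNPs retained (default 2).
#' @return A list of class `pruning_trace`: `steps` (tibble of removed_rsid,
#'   locus, q_before, p_het_before), `final_estimate`, `final_q`, `final_m`,
#'   `final_instrument`, `floor_reached`.
#' @export
prune_heterogeneity <- function(h, p_threshold = 0.05, floor = 2) {
  stopifnot(inherits(h, "harmonized_instrument"))
  if (h$m_used < 2) stop("pruning requires at least 2 SNPs", call. = FALSE)
  if (floor < 2) stop("pruning floor must be >= 2", call. = FALSE)
  steps <- list()
  floor_reached <- FALSE
  repeat {
    e <- estimate_causal_effect(h)
    het <- q_statistic(h, e)
    if (het$p_het >= p_threshold) break
    if (h$m_used <= floor) {
      floor_reached <- TRUE
      warning(sprintf(
        "pruning floor of %d SNPs reached with heterogeneity still significant (p = %.3g)",
        floor, het$p_het), call. = FALSE)
      break
    }
    contrib <- het$per_snp_contrib
    ord <- order(-contrib$contribution, contrib$rsid)
    worst <- contrib$rsid[ord[1]]
    locus <- if ("locus" %in% names(h$pairs)) {
      h$pairs$locus[match(worst, h$pairs$rsid)]
    } else NA_character_
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, removed_rsid = worst, locus = locus,
      q_before = het$q, p_het_before = het$p_het)
    h <- .drop_snp(h, worst)
  }
  structure(list(
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), removed_rsid = character(),
                     locus = character(), q_before = double(),
                     p_het_before = double()),
    final_estimate = e,
    final_q = het,
    final_m = h$m_used,
    final_instrument = h,
    floor_reached = floor_reached
  ), class = "pruning_trace")
}

#' @export
print.pruning_trace <- function(x, ...) {
  cat(sprintf("Pruning trace: %d SNP(s) removed, final M = %d, final p-het = %.3g%s\n",
              nrow(x$steps), x$final_m, x$final_q$p_het,
              if (x$floor_reached) " [floor reached]" else ""))
  if (nrow(x$steps) > 0) print(x$steps)
  invisible(x)
}

#' Write the pruning audit table
#'
#' One row per removal step plus a final summary row.
#'
#' @param trace A `pruning_trace`.
#' @param path Output path (tab-separated).
#' @export
write_pruning_audit <- function(trace, path) {
  stopifnot(inherits(trace, "pruning_trace"))
  final <- tibble::tibble(
    step = NA_integer_, removed_rsid = "(final)",
    locus = sprintf("M=%d", trace$final_m),
    q_before = trace$final_q$q, p_het_before = trace$final_q$p_het)
  readr::write_delim(dplyr::bind_rows(trace$steps, final), path,
                     delim = "\t", na = ".")
  invisible(path)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect once per SNP excluded, to check that no
#' single variant drives the result.
#'
#' @param h A `harmonized_instrument` with at least 2 SNPs.
#' @return A tibble with one row per excluded SNP: `excluded_rsid`, `m_used`,
#'   `alpha`, `se_alpha`, `p_assoc`, `or_point`, `or_low`, `or_high`.
#' @export
leave_one_out <- function(h) {
  stopifnot(inherits(h, "harmonized_instrument"))
  if (h$m_used < 2) stop("leave-one-out requires at least 2 SNPs", call. = FALSE)
  rows <- lapply(h$pairs$rsid, function(r) {
    e <- estimate_causal_effect(.drop_snp(h, r))
    tibble::tibble(excluded_rsid = r, m_used = e$m_used, alpha = e$alpha,
                   se_alpha = e$se_alpha, p_assoc = e$p_assoc,
                   or_point = e$or_point, or_low = e$or_low, or_high = e$or_high)
  })
  dplyr::bind_rows(rows)
}
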