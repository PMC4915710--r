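# Closed-form summary-statistics causal estimator for a weighted GRS
# instrument, plus presentation helpers and the instrument-strength F.

.z975 <- 1.959964  # Phi^{-1}(0.975); used for all 95% intervals

.pairs_of <- function(h) {
  if (inherits(h, "harmonized_instrument")) return(h$pairs)
  if (is.data.frame(h)) {
    .check_columns(h, c("omega", "beta", "se_beta"), "pairs")
    return(tibble::as_tibble(h))
  }
  stop("expected a harmonized_instrument or a data frame with omega/beta/se_beta",
       call. = FALSE)
}

#' Inverse-variance-weighted causal estimate from summary statistics
#'
#' For a set of uncorrelated instrument SNPs with exposure weights
#' \eqn{\omega_j} and per-allele outcome effects \eqn{\beta_j} (standard error
#' \eqn{se_{\beta j}}), the causal effect of a one-unit increase in the
#' (ln-scale) exposure is approximated by
#' \deqn{\alpha = \frac{\sum_j \omega_j \beta_j se_{\beta j}^{-2}}
#'                     {\sum_j \omega_j^2 se_{\beta j}^{-2}}, \qquad
#'       se_\alpha = \sqrt{1 / \sum_j \omega_j^2 se_{\beta j}^{-2}},}
#' the slope (and fixed-effect standard error) of the weighted regression of
#' \eqn{\beta} on \eqn{\omega} through the origin with weights
#' \eqn{se_\beta^{-2}}. Inference is a large-sample Wald test against the
#' standard normal.
#'
#' @param h A `harmonized_instrument`, or a data frame with columns `omega`,
#'   `beta`, `se_beta` (one row per SNP).
#' @param outcome_type `"binary"` (effects are log-odds-ratios; an OR with 95%
#'   CI is attached) or `"quantitative"`. Defaults to the harmonized object's
#'   type.
#' @return An object of class `causal_estimate`: `alpha`, `se_alpha`, `z`,
#'   `p_assoc`, `m_used`, `or_point`/`or_low`/`or_high` (binary; the same
#'   exponentiated interval is reported as `est`/`ci_low`/`ci_high` for
#'   quantitative outcomes on the identity scale), `scale_note`.
#' @export
estimate_causal_effect <- function(h, outcome_type = NULL) {
  pairs <- .pairs_of(h)
  outcome_type <- outcome_type %||%
    (if (inherits(h, "harmonized_instrument")) h$outcome_type else "binary")
  m <- nrow(pairs)
  if (m == 0) stop("empty instrument: no SNPs to estimate from", call. = FALSE)
  if (any(pairs$se_beta <= 0)) stop("se_beta must be > 0", call. = FALSE)
  if (all(pairs$omega == 0)) {
    stop("degenerate instrument: all omega weights are zero", call. = FALSE)
  }
  w2 <- pairs$se_beta^-2
  denom <- sum(pairs$omega^2 * w2)
  alpha <- sum(pairs$omega * pairs$beta * w2) / denom
  se_alpha <- sqrt(1 / denom)
  z <- alpha / se_alpha
  p <- 2 * pnorm(-abs(z))
  est <- structure(list(
    alpha = alpha, se_alpha = se_alpha, z = z, p_assoc = p, m_used = m,
    outcome_type = outcome_type,
    or_point = exp(alpha),
    or_low = exp(alpha - .z975 * se_alpha),
    or_high = exp(alpha + .z975 * se_alpha),
    scale_note = "per_unit_lnCRP",
    outcome_name = if (inherits(h, "harmonized_instrument")) h$outcome_name else NA_character_,
    grs_label = if (inherits(h, "harmonized_instrument")) h$grs_label else NA_character_
  ), class = "causal_estimate")
  est
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("Causal estimate (%s, M = %d, scale %s)\n",
              x$outcome_type, x$m_used, x$scale_note))
  cat(sprintf("  alpha = %.4f (se %.4f), z = %.3f, p = %.3g\n",
              x$alpha, x$se_alpha, x$z, x$p_assoc))
  if (identical(x$outcome_type, "binary")) {
    cat(sprintf("  OR %.2f (95%% CI %.2f to %.2f)\n",
                x$or_point, x$or_low, x$or_high))
  } else {
    cat(sprintf("  effect %.3f (95%% CI %.3f to %.3f)\n",
                x$alpha, x$alpha - .z975 * x$se_alpha, x$alpha + .z975 * x$se_alpha))
  }
  invisible(x)
}

#' Rescale a causal estimate to a different exposure unit
#'
#' Multiplies `alpha` and `se_alpha` by `factor` and recomputes the
#' exponentiated presentation. The Wald z (and hence `p_assoc`) is invariant.
#' `factor = 0.1` converts the canonical per-unit ln-exposure scale to a
#' per-10-sympercent (10 s%) presentation, since 0.1 ln-units is a symmetric
#' 10% change in the exposure.
#'
#' @param e A `causal_estimate`.
#' @param factor Positive rescaling factor.
#' @return A rescaled `causal_estimate` with `scale_note` updated.
#' @export
rescale_effect <- function(e, factor) {
  stopifnot(inherits(e, "causal_estimate"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("factor must be a positive scalar", call. = FALSE)
  }
  e$alpha <- e$alpha * factor
  e$se_alpha <- e$se_alpha * factor
  e$or_point <- exp(e$alpha)
  e$or_low <- exp(e$alpha - .z975 * e$se_alpha)
  e$or_high <- exp(e$alpha + .z975 * e$se_alpha)
  e$scale_note <- if (isTRUE(all.equal(factor, 0.1))) "per_10_spercent" else
    sprintf("per_unit_lnCRP_x%g", factor)
  e
}

#' Instrument-strength F-statistic
#'
#' \deqn{F = \frac{R^2 (n - 1 - K)}{(1 - R^2) K}}
#' where \eqn{R^2} is the proportion of exposure variance explained by the
#' GRS, \eqn{n} the exposure-association sample size, and \eqn{K} the number
#' of instruments in the first-stage model (1 for a single GRS). As a rule of
#' thumb, F above ten indicates weak-instrument bias is unlikely.
#'
#' @param r2 Proportion of exposure variance explained, in (0, 1).
#' @param n Sample size (must exceed `k + 1`).
#' @param k Number of instruments in the model (default 1).
#' @return The F value (unrounded; round at presentation).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (!is.numeric(r2) || any(r2 <= 0 | r2 >= 1)) {
    stop("r2 must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(n <= k + 1)) stop("n must exceed k + 1", call. = FALSE)
  (r2 * (n - 1 - k)) / ((1 - r2) * k)
}
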