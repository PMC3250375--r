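#' Population attributable risk (Levin's formula)
#'
#' Fraction of cases in the population attributable to the risk allele,
#' computed from an odds ratio and the exposure prevalence by Levin's
#' formula \eqn{PAR = p(OR - 1) / (1 + p(OR - 1))}, where p is the
#' risk-allele frequency in the control population (taken as the exposure
#' prevalence). The confidence bounds substitute the OR's CI bounds into the
#' same formula. A protective allele (OR < 1) yields a negative PAR, returned
#' as-is with a flag rather than clamped.
#'
#' @param or An odds ratio: a single positive number, an `or_result`, a
#'   `meta_or`, or an `snp_meta` fit (its selected model is used).
#' @param exposure_frequency Risk-allele frequency in the reference
#'   population, in \[0, 1\]; typically the fixed-effects pooled control
#'   frequency from [pooled_proportion()] (a `pooled_proportion` object is
#'   accepted directly).
#' @return Object of class `par_result` with fields `par`, `ci_low`,
#'   `ci_high` (NA when `or` carries no CI), `exposure_frequency`,
#'   `protective`.
#' @examples
#' par_levin(3.09, 0.374)   # 43.9%
#' par_levin(2.13, 0.374)   # 29.7%
#' @export
par_levin <- function(or, exposure_frequency) {
  if (inherits(exposure_frequency, "pooled_proportion")) {
    exposure_frequency <- exposure_frequency$estimate
  }
  stopifnot(is.numeric(exposure_frequency), length(exposure_frequency) == 1,
            exposure_frequency >= 0, exposure_frequency <= 1)
  if (inherits(or, "snp_meta")) or <- selected_fit(or)
  if (inherits(or, "meta_or")) {
    est <- or$summary_or; lo <- or$ci_low; hi <- or$ci_high
  } else if (inherits(or, "or_result")) {
    est <- or$estimate; lo <- or$ci_low; hi <- or$ci_high
  } else {
    stopifnot(is.numeric(or), length(or) == 1)
    est <- or; lo <- NA_real_; hi <- NA_real_
  }
  if (est <= 0) stop("odds ratio must be positive", call. = FALSE)
  levin <- function(r) {
    exposure_frequency * (r - 1) / (1 + exposure_frequency * (r - 1))
  }
  structure(list(
    par = levin(est),
    ci_low = if (is.na(lo)) NA_real_ else levin(lo),
    ci_high = if (is.na(hi)) NA_real_ else levin(hi),
    exposure_frequency = exposure_frequency,
    protective = est < 1
  ), class = "par_result")
}

#' @export
print.par_result <- function(x, ...) {
  cat(sprintf("Population attributable risk = %.1f%%", 100 * x$par))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.1f%%-%.1f%%)", 100 * x$ci_low, 100 * x$ci_high))
  }
  cat(sprintf("  [exposure frequency %.3f]\n", x$exposure_frequency))
  if (x$protective) cat("Note: OR < 1 — protective allele, PAR negative\n")
  invisible(x)
}
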