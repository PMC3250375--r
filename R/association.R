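## Per-study case-control association statistics on 2x2 tables.

Z95 <- stats::qnorm(0.975)

## Internal constructor shared by all OR-producing operations.
## cells: c(a, b, c, d) = (case exposed, case unexposed, control exposed,
## control unexposed) AFTER any continuity correction.
new_or_result <- function(cells, method, p_value, corrected) {
  cells <- unname(as.numeric(cells))
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  log_or <- log(a) - log(b) - log(cc) + log(d)
  se <- sqrt(sum(1 / cells))
  structure(list(
    estimate = exp(log_or),
    log_or = log_or,
    se_log = se,
    ci_low = exp(log_or - Z95 * se),
    ci_high = exp(log_or + Z95 * se),
    p_value = p_value,
    method = method,
    continuity_corrected = corrected,
    table = matrix(cells, 2, 2, byrow = TRUE,
                   dimnames = list(c("case", "control"),
                                   c("exposed", "unexposed")))
  ), class = "or_result")
}

## Haldane-Anscombe correction: add 0.5 to every cell of the affected table
## only when some cell is zero. Returns list(cells, corrected).
correct_zero_cells <- function(cells) {
  if (any(cells == 0)) list(cells = cells + 0.5, corrected = TRUE)
  else list(cells = cells, corrected = FALSE)
}

## Pearson chi-square p on a 2x2 without continuity correction; NA-safe for
## degenerate margins (monomorphic tables give p = 1: no evidence either way).
pearson_p <- function(cells) {
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  n <- sum(cells)
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom == 0) return(1)
  x2 <- n * (a * d - b * cc)^2 / denom
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

or_from_2x2 <- function(a, b, cc, d, method) {
  p <- pearson_p(as.numeric(c(a, b, cc, d)))
  corr <- correct_zero_cells(c(a, b, cc, d))
  new_or_result(corr$cells, method, p, corr$corrected)
}

#' Allelic (allele-contrast) odds ratio
#'
#' Case-control association of the risk allele: the genotype counts of each
#' group are collapsed to allele counts (2n alleles per group) and the odds
#' ratio of carrying the risk allele T rather than the major allele G is
#' computed from the 2x2 allele table. The standard error of the log odds
#' ratio uses Woolf's formula \eqn{\sqrt{\sum 1/cell}}; the 95% CI is normal
#' on the log scale; the p-value is the Pearson chi-square test on the allele
#' table (1 df, two-sided, no Yates correction). If any cell of the table is
#' zero, 0.5 is added to all four cells (Haldane-Anscombe) and the result is
#' flagged.
#'
#' @param case,control [genotype_counts] for the case and control groups;
#'   both must contain at least one subject.
#' @return An object of class `or_result` with fields `estimate`, `log_or`,
#'   `se_log`, `ci_low`, `ci_high`, `p_value`, `method`,
#'   `continuity_corrected` and the underlying 2x2 `table`.
#' @examples
#' allelic_or(genotype_counts(26, 81, 74), genotype_counts(79, 94, 30))
#' @export
allelic_or <- function(case, control) {
  case <- as_genotype_counts(case)
  control <- as_genotype_counts(control)
  if (sum(case) == 0 || sum(control) == 0) {
    stop("allelic_or: a group with zero subjects is degenerate", call. = FALSE)
  }
  ac <- allele_counts(case)
  an <- allele_counts(control)
  or_from_2x2(ac["t"], ac["g"], an["t"], an["g"], "allelic_woolf")
}

#' Case-case allelic odds ratio between two disease subtypes
#'
#' Allele-contrast odds ratio of subtype A versus subtype B, used to quantify
#' genotype-phenotype heterogeneity between disease subtypes without
#' reference to controls. Identical machinery to [allelic_or()] with subtype
#' B playing the control role; tagged `case_case_allelic`.
#'
#' @param cases_a,cases_b [genotype_counts] for the two case groups.
#' @return An `or_result`.
#' @export
case_case_allelic_or <- function(cases_a, cases_b) {
  cases_a <- as_genotype_counts(cases_a)
  cases_b <- as_genotype_counts(cases_b)
  if (sum(cases_a) == 0 || sum(cases_b) == 0) {
    stop("case_case_allelic_or: a group with zero subjects is degenerate",
         call. = FALSE)
  }
  aa <- allele_counts(cases_a)
  ab <- allele_counts(cases_b)
  or_from_2x2(aa["t"], aa["g"], ab["t"], ab["g"], "case_case_allelic")
}

#' Genotype-specific odds ratios (GT vs GG and TT vs GG)
#'
#' Odds ratios for the heterozygous and risk-homozygous genotypes with the
#' common homozygote GG as baseline. With a single categorical predictor and
#' no covariates the maximum-likelihood logistic-regression estimates equal
#' the cross-tabulation odds ratios, so each contrast is computed from its
#' 2x2 sub-table with a Woolf CI; the equivalence with the logistic solver is
#' exercised in the test suite. A zero baseline cell triggers the
#' Haldane-Anscombe correction on the affected sub-table, flagged in the
#' result.
#'
#' @inheritParams allelic_or
#' @return List with components `gt_vs_gg` and `tt_vs_gg`, each an
#'   `or_result` (methods `genotype_gt_vs_gg`, `genotype_tt_vs_gg`).
#' @examples
#' genotype_specific_ors(genotype_counts(26, 81, 74),
#'                       genotype_counts(79, 94, 30))
#' @export
genotype_specific_ors <- function(case, control) {
  case <- as_genotype_counts(case)
  control <- as_genotype_counts(control)
  if (case[["gg"]] == 0 && control[["gg"]] == 0) {
    stop("genotype_specific_ors: baseline genotype GG absent from both groups",
         call. = FALSE)
  }
  list(
    gt_vs_gg = or_from_2x2(case[["gt"]], case[["gg"]],
                           control[["gt"]], control[["gg"]],
                           "genotype_gt_vs_gg"),
    tt_vs_gg = or_from_2x2(case[["tt"]], case[["gg"]],
                           control[["tt"]], control[["gg"]],
                           "genotype_tt_vs_gg")
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR [%s] = %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$p_value,
              if (x$continuity_corrected) " [continuity corrected]" else ""))
  invisible(x)
}
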