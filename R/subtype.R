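## Genotype-phenotype heterogeneity between two disease subtypes:
## case-only logistic regression, case-case OR meta-analysis and
## pooled-frequency difference testing.

#' Case-only logistic test of subtype heterogeneity
#'
#' Tests whether a variant's effect differs between two disease subtypes
#' using cases only: logistic regression of the subtype indicator (subtype A
#' coded 1) on genotype. Under `additive_dose` coding the genotype enters as
#' the risk-allele count 0/1/2 and the test is the Wald z-test of the dose
#' coefficient. Under `genotypic` coding two indicators (GT and TT, baseline
#' GG) enter and the test is the 2-df likelihood-ratio test.
#'
#' The maximum-likelihood fit uses iteratively reweighted least squares on
#' the aggregated genotype table. Complete separation (a genotype class
#' observed in only one subtype driving the MLE to infinity) is detected and
#' flagged; the p-value is then reported as `NA`.
#'
#' @param cases_a,cases_b [genotype_counts] of the two case groups; the model
#'   outcome is membership of group A.
#' @param coding `"additive_dose"` (default) or `"genotypic"`.
#' @return Object of class `case_only_result` with fields `beta`, `se`
#'   (length 2 under genotypic coding), `wald_z` (NA under genotypic coding),
#'   `p_value`, `coding`, `separated`.
#' @examples
#' case_only_logistic(genotype_counts(26, 81, 74), genotype_counts(42, 77, 79))
#' @export
case_only_logistic <- function(cases_a, cases_b,
                               coding = c("additive_dose", "genotypic")) {
  coding <- match.arg(coding)
  cases_a <- as_genotype_counts(cases_a)
  cases_b <- as_genotype_counts(cases_b)
  if (sum(cases_a) == 0 || sum(cases_b) == 0) {
    stop("case_only_logistic: both case groups must be non-empty",
         call. = FALSE)
  }
  d <- data.frame(
    subtype = rep(c(1, 0), each = 3),
    dose = rep(0:2, 2),
    count = c(as.integer(cases_a), as.integer(cases_b))
  )
  d <- d[d$count > 0, ]
  d$geno <- factor(d$dose, levels = 0:2, labels = c("gg", "gt", "tt"))
  fit <- switch(coding,
    additive_dose = stats::glm(subtype ~ dose, family = stats::binomial(),
                               data = d, weights = count),
    genotypic = stats::glm(subtype ~ geno, family = stats::binomial(),
                           data = d, weights = count))
  if (!fit$converged) {
    stop("case_only_logistic: IRLS failed to converge after ",
         fit$iter, " iterations", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  beta <- cf[-1, "Estimate"]
  se <- cf[-1, "Std. Error"]
  ## MLE diverging => separation; Wald inference meaningless
  separated <- any(abs(beta) > 15) || any(se > 1e3)
  if (coding == "additive_dose") {
    z <- unname(beta / se)
    p <- if (separated) NA_real_ else 2 * stats::pnorm(-abs(z))
  } else {
    z <- NA_real_
    null_fit <- stats::glm(subtype ~ 1, family = stats::binomial(),
                           data = d, weights = count)
    lrt <- null_fit$deviance - fit$deviance
    p <- if (separated) NA_real_ else
      stats::pchisq(lrt, df = length(beta), lower.tail = FALSE)
  }
  structure(list(beta = unname(beta), se = unname(se), wald_z = z,
                 p_value = p, coding = coding, separated = separated),
            class = "case_only_result")
}

#' @export
print.case_only_result <- function(x, ...) {
  cat(sprintf("Case-only heterogeneity test (%s coding)\n", x$coding))
  if (x$coding == "additive_dose") {
    cat(sprintf("  beta = %.4f (SE %.4f), z = %.3f, p = %.3g\n",
                x$beta, x$se, x$wald_z, x$p_value))
  } else {
    cat(sprintf("  beta(GT) = %.4f, beta(TT) = %.4f, 2-df LRT p = %.3g\n",
                x$beta[1], x$beta[2], x$p_value))
  }
  if (x$separated) cat("  WARNING: complete separation detected\n")
  invisible(x)
}

#' Compare the genetic effect between two disease subtypes across studies
#'
#' Restricts the dataset to studies containing both case subtypes and
#' performs three linked analyses: (1) fixed-effects pooled risk-allele
#' frequency in each subtype; (2) a two-sided z-test of the difference of the
#' two pooled frequencies using their pooled standard errors; (3) an
#' inverse-variance fixed-effects meta-analysis of the per-study case-case
#' allelic log odds ratios (subtype A vs subtype B) with Cochran's Q and
#' I-squared. Per-study case-only logistic tests are also reported.
#'
#' @param dataset An `snp_dataset` with at least one study containing both
#'   `neovascular_amd` and `pcv` case groups.
#' @param subtype_a,subtype_b The two case phenotype labels; defaults
#'   compare neovascular AMD (A) against PCV (B).
#' @return Object of class `subtype_comparison` with components
#'   `pooled_freq_a`, `pooled_freq_b` ([pooled_proportion] objects),
#'   `freq_diff`, `freq_diff_z`, `freq_diff_p`, `case_case_meta` (a
#'   `meta_or`), `per_study` (data frame of case-case ORs and case-only
#'   p-values), `studies` (the ids used).
#' @examples
#' ds <- read_dataset(system.file("extdata", "table2.csv", package = "snpmeta"))
#' compare_subtypes(ds)
#' @export
compare_subtypes <- function(dataset, subtype_a = "neovascular_amd",
                             subtype_b = "pcv") {
  stopifnot(inherits(dataset, "snp_dataset"))
  subtype_a <- match.arg(subtype_a, PHENOTYPES)
  subtype_b <- match.arg(subtype_b, PHENOTYPES)
  ids <- intersect(study_ids(dataset, subtype_a), study_ids(dataset, subtype_b))
  if (length(ids) == 0) {
    stop("no study contains both '", subtype_a, "' and '", subtype_b,
         "' groups", call. = FALSE)
  }
  ga <- lapply(ids, function(s) study_group(dataset, s, subtype_a))
  gb <- lapply(ids, function(s) study_group(dataset, s, subtype_b))

  pool_freq <- function(groups) {
    al <- vapply(groups, allele_counts, numeric(2))
    pooled_proportion(al["t", ], colSums(al), "allele")
  }
  pa <- pool_freq(ga)
  pb <- pool_freq(gb)
  se_a <- (pa$ci_high - pa$ci_low) / (2 * Z95)
  se_b <- (pb$ci_high - pb$ci_low) / (2 * Z95)
  z <- (pa$estimate - pb$estimate) / sqrt(se_a^2 + se_b^2)
  cc <- mapply(function(a, b) {
    r <- case_case_allelic_or(a, b)
    c(r$log_or, r$se_log^2, r$estimate, r$ci_low, r$ci_high)
  }, ga, gb)
  meta <- iv_pooled_or(cc[1, ], cc[2, ])
  caseonly_p <- mapply(function(a, b) case_only_logistic(a, b)$p_value, ga, gb)
  per_study <- data.frame(study_id = ids, or = cc[3, ], ci_low = cc[4, ],
                          ci_high = cc[5, ], case_only_p = caseonly_p,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(subtype_a = subtype_a, subtype_b = subtype_b, studies = ids,
                 pooled_freq_a = pa, pooled_freq_b = pb,
                 freq_diff = pa$estimate - pb$estimate, freq_diff_z = z,
                 freq_diff_p = 2 * stats::pnorm(-abs(z)),
                 case_case_meta = meta, per_study = per_study),
            class = "subtype_comparison")
}

#' @export
print.subtype_comparison <- function(x, ...) {
  cat(sprintf("Subtype comparison: %s (A) vs %s (B), %d dual-subtype stud%s\n",
              x$subtype_a, x$subtype_b, length(x$studies),
              if (length(x$studies) == 1) "y" else "ies"))
  cat(sprintf("Pooled risk-allele frequency: %.1f%% vs %.1f%% (diff p = %.2g)\n",
              100 * x$pooled_freq_a$estimate, 100 * x$pooled_freq_b$estimate,
              x$freq_diff_p))
  cat("Case-case allele contrast:\n  ")
  print(x$case_case_meta)
  invisible(x)
}
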