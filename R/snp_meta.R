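#' Fit a case-control allele-contrast meta-analysis
#'
#' The package's central fitting function. For one case phenotype it
#' assembles the per-study 2x2 allele tables from every study in the dataset
#' that has both that case group and a control group, computes per-study
#' allelic odds ratios, and pools them under both the Mantel-Haenszel
#' fixed-effects model and (for two or more studies) the DerSimonian-Laird
#' random-effects model. Under `model = "auto"` the reported model follows
#' the conventional heterogeneity rule: fixed effects when the Q-statistic
#' p-value is at least 0.1, random effects otherwise.
#'
#' @param dataset An `snp_dataset` (see [read_dataset()]).
#' @param phenotype Case phenotype to pool: `"neovascular_amd"` or `"pcv"`.
#' @param model `"auto"` (heterogeneity-driven choice), `"fixed"` or
#'   `"random"`.
#' @return An object of class `snp_meta` with components
#'   \describe{
#'     \item{phenotype}{the case phenotype pooled}
#'     \item{studies}{data frame of per-study ORs, 95% CIs, p-values and
#'       normalised fixed-effects weights}
#'     \item{fixed}{the Mantel-Haenszel [mh_pooled_or()] fit}
#'     \item{random}{the [dl_pooled_or()] fit, or `NULL` for a single study}
#'     \item{model_used}{which model the `auto` rule (or the user) selected}
#'   }
#'   Methods: `print`, `summary`, `coef` (pooled log OR), `confint`,
#'   `weights`, `plot` (forest plot).
#' @examples
#' ds <- read_dataset(system.file("extdata", "table2.csv", package = "snpmeta"))
#' fit <- snp_meta(ds, "neovascular_amd")
#' fit
#' coef(fit)
#' confint(fit)
#' @export
snp_meta <- function(dataset, phenotype = c("neovascular_amd", "pcv"),
                     model = c("auto", "fixed", "random")) {
  phenotype <- match.arg(phenotype)
  model <- match.arg(model)
  pairs <- case_control_pairs(dataset, phenotype)
  tables <- lapply(pairs, function(p) allele_table(p$case, p$control))
  per_study <- lapply(pairs, function(p) allelic_or(p$case, p$control))
  fixed <- mh_pooled_or(tables)
  random <- if (length(tables) >= 2) dl_pooled_or(tables) else NULL
  model_used <- switch(model,
    fixed = "mantel_haenszel_fixed",
    random = {
      if (is.null(random)) {
        stop("random-effects model requested but only one study available",
             call. = FALSE)
      }
      "dersimonian_laird_random"
    },
    auto = if (!is.null(random) && !is.na(fixed$p_het) && fixed$p_het < 0.1) {
      "dersimonian_laird_random"
    } else {
      "mantel_haenszel_fixed"
    })
  studies <- data.frame(
    study_id = names(pairs),
    or = vapply(per_study, `[[`, numeric(1), "estimate"),
    ci_low = vapply(per_study, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(per_study, `[[`, numeric(1), "ci_high"),
    p_value = vapply(per_study, `[[`, numeric(1), "p_value"),
    weight = unname(fixed$weights),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(phenotype = phenotype, studies = studies, tables = tables,
                 fixed = fixed, random = random, model_used = model_used),
            class = "snp_meta")
}

selected_fit <- function(x) {
  if (x$model_used == "dersimonian_laird_random") x$random else x$fixed
}

#' @export
print.snp_meta <- function(x, ...) {
  cat(sprintf("Allele-contrast meta-analysis: %s vs control (%d stud%s)\n",
              x$phenotype, nrow(x$studies),
              if (nrow(x$studies) == 1) "y" else "ies"))
  print(selected_fit(x))
  invisible(x)
}

#' @export
summary.snp_meta <- function(object, ...) {
  structure(object, class = c("summary.snp_meta", class(object)))
}

#' @export
print.summary.snp_meta <- function(x, ...) {
  cat(sprintf("Allele-contrast meta-analysis: %s vs control\n\n", x$phenotype))
  st <- x$studies
  st$or <- sprintf("%.2f", st$or)
  st$ci <- sprintf("%.2f-%.2f", x$studies$ci_low, x$studies$ci_high)
  st$p_value <- sprintf("%.2g", x$studies$p_value)
  st$weight <- sprintf("%.1f%%", 100 * x$studies$weight)
  print(st[, c("study_id", "or", "ci", "p_value", "weight")],
        row.names = FALSE)
  cat("\nFixed effects (Mantel-Haenszel):\n  ")
  print(x$fixed)
  if (!is.null(x$random)) {
    cat("Random effects (DerSimonian-Laird):\n  ")
    print(x$random)
  }
  cat(sprintf("Model selected: %s\n", x$model_used))
  invisible(x)
}

#' @export
coef.snp_meta <- function(object, ...) {
  fit <- selected_fit(object)
  c(log_or = fit$log_or)
}

#' @export
confint.snp_meta <- function(object, parm, level = 0.95, ...) {
  fit <- selected_fit(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(exp(fit$log_or + c(-1, 1) * z * fit$se_log), 1, 2,
              dimnames = list("or", sprintf("%g %%", 100 * c((1 - level) / 2,
                                                             1 - (1 - level) / 2))))
  m
}

#' @export
weights.snp_meta <- function(object, ...) {
  stats::setNames(object$studies$weight, object$studies$study_id)
}

#' Forest plot of a fitted meta-analysis
#'
#' Draws the conventional forest plot: one square per study (area
#' proportional to its pooling weight) with a 95% CI bar, and an unshaded
#' diamond for the pooled odds ratio, on a log-scaled axis.
#'
#' @param x An `snp_meta` fit.
#' @param xlab Axis label.
#' @param main Plot title; defaults to the phenotype.
#' @param ... Further arguments passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.snp_meta <- function(x, xlab = "Odds ratio (log scale)",
                          main = NULL, ...) {
  st <- x$studies
  fit <- selected_fit(x)
  k <- nrow(st)
  ylim <- c(0, k + 1.5)
  xlim <- range(st$ci_low, st$ci_high, fit$ci_low, fit$ci_high, 1)
  graphics::plot(NA, xlim = xlim, ylim = ylim, log = "x", yaxt = "n",
                 xlab = xlab, ylab = "",
                 main = if (is.null(main)) x$phenotype else main, ...)
  graphics::abline(v = 1, lty = 3)
  ys <- rev(seq_len(k)) + 0.5
  graphics::segments(st$ci_low, ys, st$ci_high, ys)
  graphics::points(st$or, ys, pch = 15, cex = 0.8 + 2 * sqrt(st$weight))
  graphics::axis(2, at = c(ys, 0.5), labels = c(st$study_id, "Summary"),
                 las = 1, tick = FALSE)
  dx <- exp(c(log(fit$ci_low), log(fit$summary_or), log(fit$ci_high),
              log(fit$summary_or), log(fit$ci_low)))
  graphics::polygon(dx, 0.5 + c(0, 0.3, 0, -0.3, 0), border = "black",
                    col = NA)
  invisible(x)
}
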