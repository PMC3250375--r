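## Cross-study pooling: Mantel-Haenszel and DerSimonian-Laird odds-ratio
## meta-analysis, Cochran's Q / I-squared, and fixed-effects pooling of
## proportions.

#' Build a 2x2 allele table for one study
#'
#' Collapses one case and one control group to the stratified 2x2 allele
#' table consumed by the pooling operations: rows case/control, columns
#' risk (T) / non-risk (G) allele counts.
#'
#' @inheritParams allelic_or
#' @return 2x2 numeric matrix.
#' @export
allele_table <- function(case, control) {
  ac <- allele_counts(case)
  an <- allele_counts(control)
  matrix(c(ac["t"], ac["g"], an["t"], an["g"]), 2, 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("risk", "nonrisk")))
}

## Validate a list of 2x2 tables; returns a 4-column matrix (a, b, c, d) =
## (case risk, case non-risk, control risk, control non-risk).
as_table_matrix <- function(tables) {
  if (length(tables) == 0) stop("no 2x2 tables supplied", call. = FALSE)
  m <- t(vapply(tables, function(tb) {
    tb <- as.matrix(tb)
    if (!all(dim(tb) == c(2, 2)) || any(tb < 0)) {
      stop("each stratum must be a non-negative 2x2 table", call. = FALSE)
    }
    as.numeric(t(tb))
  }, numeric(4)))
  colnames(m) <- c("a", "b", "c", "d")
  if (any(rowSums(m[, c(1, 2), drop = FALSE]) == 0) ||
      any(rowSums(m[, c(3, 4), drop = FALSE]) == 0)) {
    stop("a stratum has an empty case or control margin", call. = FALSE)
  }
  m
}

## Per-stratum Woolf log-ORs and variances, Haldane-Anscombe corrected
## per affected stratum only.
woolf_components <- function(m) {
  zero <- rowSums(m == 0) > 0
  mc <- m + 0.5 * zero
  list(y = log(mc[, "a"]) - log(mc[, "b"]) - log(mc[, "c"]) + log(mc[, "d"]),
       v = rowSums(1 / mc),
       corrected = zero)
}

## Cochran's Q of effects y with weights w about their weighted mean.
cochran_q <- function(y, w) {
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  df <- length(y) - 1L
  list(q = q, df = df,
       p = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

new_meta_or <- function(log_or, se, weights, het, tau2, model, k) {
  z <- log_or / se
  structure(list(
    summary_or = exp(log_or),
    log_or = log_or,
    se_log = se,
    ci_low = exp(log_or - Z95 * se),
    ci_high = exp(log_or + Z95 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    weights = weights / sum(weights),
    q_stat = het$q,
    df = het$df,
    p_het = het$p,
    i_squared = het$i2,
    tau_squared = tau2,
    model = model,
    k = k
  ), class = "meta_or")
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Pools stratified 2x2 allele tables with the Mantel-Haenszel estimator
#' \eqn{OR_{MH} = \sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i}. The
#' variance of the log pooled OR uses the Robins-Breslow-Greenland estimator,
#' valid under both sparse-data and large-stratum asymptotics. Between-study
#' heterogeneity is summarised by Cochran's Q computed on the per-study Woolf
#' log-ORs with inverse-variance weights about the inverse-variance mean
#' (chi-square with k-1 df) and by I-squared; heterogeneity is conventionally
#' declared at `p_het < 0.1`.
#'
#' A single stratum reduces exactly to that study's crude allelic OR with
#' Q = 0 and df = 0.
#'
#' @param tables List of 2x2 tables as built by [allele_table()] (rows
#'   case/control, columns risk/non-risk allele counts).
#' @return Object of class `meta_or` with fields `summary_or`, `ci_low`,
#'   `ci_high`, `p_value`, normalised `weights`, `q_stat`, `df`, `p_het`,
#'   `i_squared`, `tau_squared` (0 under fixed effects) and
#'   `model = "mantel_haenszel_fixed"`.
#' @examples
#' ds <- read_dataset(system.file("extdata", "table2.csv", package = "snpmeta"))
#' tabs <- lapply(case_control_pairs(ds, "neovascular_amd"),
#'                function(p) allele_table(p$case, p$control))
#' mh_pooled_or(tabs)
#' @export
mh_pooled_or <- function(tables) {
  m <- as_table_matrix(tables)
  a <- m[, "a"]; b <- m[, "b"]; cc <- m[, "c"]; d <- m[, "d"]
  n <- a + b + cc + d
  R <- sum(a * d / n)
  S <- sum(b * cc / n)
  if (R == 0 || S == 0) {
    stop("Mantel-Haenszel estimator undefined: an allele margin is empty ",
         "in every stratum", call. = FALSE)
  }
  log_or <- log(R / S)
  ## Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n
  Q <- (b + cc) / n
  var_mh <- sum(P * a * d / n) / (2 * R^2) +
    sum(P * b * cc / n + Q * a * d / n) / (2 * R * S) +
    sum(Q * b * cc / n) / (2 * S^2)
  wc <- woolf_components(m)
  het <- cochran_q(wc$y, 1 / wc$v)
  new_meta_or(log_or, sqrt(var_mh), weights = b * cc / n, het = het,
              tau2 = 0, model = "mantel_haenszel_fixed", k = nrow(m))
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Method-of-moments random-effects pooling of stratified 2x2 allele tables.
#' Per-study Woolf log-ORs \eqn{y_i} with variances \eqn{v_i} give
#' fixed-effect weights \eqn{w_i = 1/v_i} and Cochran's Q; the between-study
#' variance is \eqn{\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))};
#' the summary is the inverse-variance mean under random-effect weights
#' \eqn{1/(v_i + \tau^2)}. When Q does not exceed its degrees of freedom,
#' \eqn{\tau^2 = 0} and the estimate coincides with the inverse-variance
#' fixed-effects estimate.
#'
#' @inheritParams mh_pooled_or
#' @return Object of class `meta_or` with `model = "dersimonian_laird_random"`.
#' @export
dl_pooled_or <- function(tables) {
  m <- as_table_matrix(tables)
  if (nrow(m) < 2) {
    stop("random-effects pooling needs at least two strata", call. = FALSE)
  }
  wc <- woolf_components(m)
  w <- 1 / wc$v
  het <- cochran_q(wc$y, w)
  tau2 <- max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (wc$v + tau2)
  log_or <- sum(w_star * wc$y) / sum(w_star)
  new_meta_or(log_or, sqrt(1 / sum(w_star)), weights = w_star, het = het,
              tau2 = tau2, model = "dersimonian_laird_random", k = nrow(m))
}

#' Inverse-variance fixed-effects pooling of log odds ratios
#'
#' Generic inverse-variance fixed-effects pooling of per-study log odds
#' ratios, used for the case-case subtype contrast where no control stratum
#' exists.
#'
#' @param log_ors Per-study log odds ratios.
#' @param variances Their sampling variances.
#' @return Object of class `meta_or` with `model = "inverse_variance_fixed"`.
#' @export
iv_pooled_or <- function(log_ors, variances) {
  stopifnot(length(log_ors) == length(variances), all(variances > 0))
  w <- 1 / variances
  het <- cochran_q(log_ors, w)
  new_meta_or(sum(w * log_ors) / sum(w), sqrt(1 / sum(w)), weights = w,
              het = het, tau2 = 0, model = "inverse_variance_fixed",
              k = length(log_ors))
}

#' @export
print.meta_or <- function(x, ...) {
  cat(sprintf("Pooled OR [%s, k=%d] = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$model, x$k, x$summary_or, x$ci_low, x$ci_high, x$p_value))
  if (x$df > 0) {
    cat(sprintf("Heterogeneity: Q = %.2f, df = %d, p = %.3g, I2 = %.1f%%",
                x$q_stat, x$df, x$p_het, x$i_squared))
    if (x$tau_squared > 0) cat(sprintf(", tau2 = %.4f", x$tau_squared))
    cat("\n")
  }
  invisible(x)
}

#' Fixed-effects pooled proportion across studies
#'
#' Pools per-study proportions (risk-allele frequencies or carrier
#' frequencies) on the raw proportion scale with inverse-variance weights:
#' study i contributes \eqn{p_i = s_i/n_i} with variance
#' \eqn{p_i(1-p_i)/n_i}. The pooled estimate is the weighted mean, its 95% CI
#' \eqn{\bar p \pm 1.96/\sqrt{\sum w_i}}, and heterogeneity is Cochran's Q of
#' the \eqn{p_i} about \eqn{\bar p} with I-squared. A degenerate study
#' proportion (0 or 1) has zero estimated variance; its weight is computed
#' from the shrunk proportion \eqn{(s_i + 0.5)/(n_i + 1)} and the result is
#' flagged.
#'
#' @param successes Per-study success counts (e.g. risk-allele counts).
#' @param totals Per-study totals (e.g. allele totals, 2n); all positive.
#' @param scale Label recording what was pooled: `"allele"` or `"carrier"`.
#' @return Object of class `pooled_proportion` with fields `estimate`,
#'   `ci_low`, `ci_high` (clamped to \[0, 1\]), `q_stat`, `df`, `p_het`,
#'   `i_squared`, `weights`, `scale`, `shrunk`.
#' @examples
#' ds <- read_dataset(system.file("extdata", "table2.csv", package = "snpmeta"))
#' ctl <- lapply(study_ids(ds), function(s) study_group(ds, s, "control"))
#' al <- vapply(ctl, allele_counts, numeric(2))
#' pooled_proportion(al["t", ], colSums(al), "allele")
#' @export
pooled_proportion <- function(successes, totals,
                              scale = c("allele", "carrier")) {
  scale <- match.arg(scale)
  stopifnot(length(successes) == length(totals), length(totals) >= 1)
  if (any(totals <= 0)) stop("all totals must be positive", call. = FALSE)
  if (any(successes < 0) || any(successes > totals)) {
    stop("successes must lie in [0, total] for every study", call. = FALSE)
  }
  p <- successes / totals
  degenerate <- p == 0 | p == 1
  p_weight <- ifelse(degenerate, (successes + 0.5) / (totals + 1), p)
  w <- totals / (p_weight * (1 - p_weight))
  est <- sum(w * p) / sum(w)
  half <- Z95 / sqrt(sum(w))
  het <- cochran_q(p, w)
  structure(list(
    estimate = est,
    ci_low = max(0, est - half),
    ci_high = min(1, est + half),
    q_stat = het$q,
    df = het$df,
    p_het = het$p,
    i_squared = het$i2,
    weights = w / sum(w),
    scale = scale,
    shrunk = any(degenerate)
  ), class = "pooled_proportion")
}

#' @export
print.pooled_proportion <- function(x, ...) {
  cat(sprintf("Pooled %s frequency = %.1f%% (95%% CI %.1f-%.1f)\n",
              x$scale, 100 * x$estimate, 100 * x$ci_low, 100 * x$ci_high))
  if (x$df > 0) {
    cat(sprintf("Heterogeneity: Q = %.2f, df = %d, p = %.3g, I2 = %.1f%%\n",
                x$q_stat, x$df, x$p_het, x$i_squared))
  }
  if (x$shrunk) cat("Note: degenerate proportion(s) shrunk for weighting\n")
  invisible(x)
}
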