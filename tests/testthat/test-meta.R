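table2_allele_tables <- function(phenotype) {
  ds <- table2_dataset()
  lapply(case_control_pairs(ds, phenotype),
         function(p) allele_table(p$case, p$control))
}

test_that("Mantel-Haenszel pooling reproduces the published summary ORs", {
  fit <- mh_pooled_or(table2_allele_tables("neovascular_amd"))
  expect_equal(round(fit$summary_or, 2), 3.09)
  expect_equal(round(fit$ci_low, 2), 2.71)
  expect_equal(round(fit$ci_high, 2), 3.51)
  expect_equal(fit$k, 4)
  expect_gt(fit$p_het, 0.1)  # no significant heterogeneity declared

  fit <- mh_pooled_or(table2_allele_tables("pcv"))
  expect_equal(round(fit$summary_or, 2), 2.13)
  expect_equal(round(fit$ci_low, 2), 1.91)
  expect_equal(round(fit$ci_high, 2), 2.38)
  expect_equal(fit$k, 6)
  expect_gt(fit$p_het, 0.1)
})

test_that("MH summary agrees with metafor's rma.mh on the same tables", {
  for (ph in c("neovascular_amd", "pcv")) {
    tabs <- table2_allele_tables(ph)
    m <- t(vapply(tabs, function(tb) as.numeric(t(tb)), numeric(4)))
    ref <- metafor::rma.mh(ai = m[, 1], bi = m[, 2], ci = m[, 3], di = m[, 4],
                           measure = "OR", correct = FALSE)
    fit <- mh_pooled_or(tabs)
    expect_equal(fit$log_or, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(fit$se_log, ref$se, tolerance = 1e-10)
  }
})

test_that("a single stratum reduces MH to the crude allelic OR", {
  ds <- table2_dataset()
  crude <- allelic_or(new_cohort$namd, new_cohort$control)
  fit <- mh_pooled_or(list(allele_table(new_cohort$namd, new_cohort$control)))
  expect_equal(fit$summary_or, crude$estimate, tolerance = 1e-12)
  expect_equal(fit$q_stat, 0, tolerance = 1e-12)
  expect_equal(fit$df, 0)
})

test_that("MH is invariant to common scaling and bounded by the study ORs", {
  tabs <- table2_allele_tables("pcv")
  fit <- mh_pooled_or(tabs)
  scaled <- mh_pooled_or(lapply(tabs, function(tb) 3 * tb))
  expect_equal(scaled$summary_or, fit$summary_or, tolerance = 1e-12)
  study_ors <- vapply(tabs, function(tb) {
    (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  }, numeric(1))
  expect_gte(fit$summary_or, min(study_ors))
  expect_lte(fit$summary_or, max(study_ors))
  expect_equal(sum(fit$weights), 1)
})

test_that("DerSimonian-Laird reduces to fixed effects when Q <= df", {
  tb <- allele_table(new_cohort$pcv, new_cohort$control)
  fit <- dl_pooled_or(list(tb, tb, tb))
  expect_equal(fit$tau_squared, 0)
  expect_equal(fit$q_stat, 0, tolerance = 1e-10)
  crude <- allelic_or(new_cohort$pcv, new_cohort$control)
  expect_equal(fit$summary_or, crude$estimate, tolerance = 1e-12)
  ## inverse-variance fixed-effect oracle computed directly in the test
  tabs <- table2_allele_tables("neovascular_amd")
  y <- vapply(tabs, function(tb) log((tb[1, 1] * tb[2, 2]) /
                                       (tb[1, 2] * tb[2, 1])), numeric(1))
  v <- vapply(tabs, function(tb) sum(1 / tb), numeric(1))
  fit <- dl_pooled_or(tabs)
  if (fit$q_stat <= fit$df) {
    expect_equal(fit$log_or, sum(y / v) / sum(1 / v), tolerance = 1e-12)
  } else {
    expect_gt(fit$tau_squared, 0)
  }
})

test_that("DL estimate, tau2 and Q agree with metafor under method = 'DL'", {
  tabs <- table2_allele_tables("pcv")
  y <- vapply(tabs, function(tb) log((tb[1, 1] * tb[2, 2]) /
                                       (tb[1, 2] * tb[2, 1])), numeric(1))
  v <- vapply(tabs, function(tb) sum(1 / tb), numeric(1))
  ref <- metafor::rma(yi = y, vi = v, method = "DL")
  fit <- dl_pooled_or(tabs)
  expect_equal(fit$log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(fit$se_log, ref$se, tolerance = 1e-10)
  expect_equal(fit$tau_squared, ref$tau2, tolerance = 1e-10)
  expect_equal(fit$q_stat, ref$QE, tolerance = 1e-10)
  expect_equal(fit$i_squared, ref$I2, tolerance = 1e-6)
})

test_that("pooled control frequencies reproduce the published block", {
  ds <- table2_dataset()
  ctl <- lapply(study_ids(ds), function(s) study_group(ds, s, "control"))
  al <- vapply(ctl, allele_counts, numeric(2))
  pp <- pooled_proportion(al["t", ], colSums(al), "allele")
  expect_equal(round(100 * pp$estimate, 1), 37.4)
  expect_equal(round(100 * pp$ci_low, 1), 35.9)
  expect_equal(round(100 * pp$ci_high, 1), 38.8)
  expect_equal(round(pp$q_stat, 2), 8.50)
  expect_equal(pp$df, 5)
  expect_equal(round(pp$i_squared, 1), 41.2)
  expect_gt(pp$p_het, 0.1)

  carr <- vapply(ctl, carrier_counts, numeric(2))
  pc <- pooled_proportion(carr["carriers", ], colSums(carr), "carrier")
  expect_equal(round(100 * pc$estimate, 1), 60.8)
  expect_equal(round(100 * pc$ci_low, 1), 58.7)
  expect_equal(round(100 * pc$ci_high, 1), 62.9)
  expect_equal(round(pc$q_stat, 1), 9.0)
  expect_equal(round(pc$i_squared, 1), 44.5)
})

test_that("pooled proportion handles single and degenerate studies", {
  pp <- pooled_proportion(30, 100, "allele")
  expect_equal(pp$estimate, 0.3)
  expect_equal(pp$q_stat, 0)
  expect_equal(pp$df, 0)
  expect_false(pp$shrunk)
  pp <- pooled_proportion(c(0, 30), c(50, 100), "carrier")
  expect_true(pp$shrunk)
  expect_true(pp$ci_low >= 0 && pp$ci_low <= pp$estimate)
  expect_true(pp$estimate <= pp$ci_high && pp$ci_high <= 1)
  expect_error(pooled_proportion(5, 0), "positive")
  expect_error(pooled_proportion(5, 4), "lie in")
})

test_that("identical studies show zero heterogeneity regardless of size", {
  pp <- pooled_proportion(rep(40, 4), rep(100, 4), "allele")
  expect_equal(pp$i_squared, 0)
  expect_equal(pp$q_stat, 0, tolerance = 1e-10)
  big <- pooled_proportion(rep(4000, 4), rep(10000, 4), "allele")
  expect_equal(big$i_squared, 0)
})
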