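test_that("case-case allelic ORs match direct 2x2 arithmetic", {
  res <- case_case_allelic_or(new_cohort$namd, new_cohort$pcv)
  expect_equal(res$estimate, (229 * 161) / (133 * 235), tolerance = 1e-12)
  expect_equal(res$method, "case_case_allelic")
  res <- case_case_allelic_or(genotype_counts(6, 20, 24),
                              genotype_counts(22, 20, 18))
  expect_equal(res$estimate, (68 * 64) / (32 * 56), tolerance = 1e-12)
  res <- case_case_allelic_or(new_cohort$pcv, new_cohort$pcv)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
})

test_that("case-case OR equals the ratio of case-control ORs", {
  ds <- table2_dataset()
  for (s in dual_subtype_studies(ds)) {
    a <- study_group(ds, s, "neovascular_amd")
    b <- study_group(ds, s, "pcv")
    ctl <- study_group(ds, s, "control")
    expect_equal(case_case_allelic_or(a, b)$estimate,
                 allelic_or(a, ctl)$estimate / allelic_or(b, ctl)$estimate,
                 tolerance = 1e-12, info = s)
  }
})

test_that("case-only logistic test behaves on the new cohort", {
  res <- case_only_logistic(new_cohort$namd, new_cohort$pcv)
  expect_equal(res$coding, "additive_dose")
  expect_equal(res$p_value, 0.297, tolerance = 0.005)
  expect_gt(res$beta, 0)  # risk-allele frequency higher in neovascular AMD
  expect_false(res$separated)
  res2 <- case_only_logistic(new_cohort$namd, new_cohort$pcv, "genotypic")
  expect_length(res2$beta, 2)
  expect_true(res2$p_value > 0 && res2$p_value < 1)
})

test_that("identical subtype distributions give beta = 0, p = 1", {
  g <- genotype_counts(30, 40, 30)
  res <- case_only_logistic(g, g)
  expect_equal(res$beta, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
})

test_that("a two-genotype collapse recovers the closed-form 2x2 log OR", {
  ## only GG and TT present: dose is 0/2, so 2 * beta = log cross-tab OR
  a <- genotype_counts(30, 0, 20)
  b <- genotype_counts(25, 0, 35)
  res <- case_only_logistic(a, b)
  expect_equal(2 * res$beta, log((20 * 25) / (30 * 35)), tolerance = 1e-8)
})

test_that("the sign of beta tracks the allele-frequency difference", {
  set.seed(17)
  for (i in 1:20) {
    pair <- random_genotype_pair()
    fa <- risk_allele_frequency(pair$case)
    fb <- risk_allele_frequency(pair$control)
    if (abs(fa - fb) < 1e-8) next
    res <- case_only_logistic(pair$case, pair$control)
    expect_equal(sign(res$beta), sign(fa - fb))
  }
})

test_that("complete separation is detected and flagged", {
  res <- case_only_logistic(genotype_counts(20, 0, 0),
                            genotype_counts(0, 0, 20))
  expect_true(res$separated)
  expect_true(is.na(res$p_value))
})

test_that("subtype comparison reproduces the published four-study block", {
  cmp <- compare_subtypes(table2_dataset())
  expect_equal(length(cmp$studies), 4)
  expect_equal(round(100 * cmp$pooled_freq_a$estimate, 1), 64.7)
  expect_equal(round(100 * cmp$pooled_freq_b$estimate, 1), 55.6)
  expect_lt(cmp$freq_diff_p, 0.001)
  expect_equal(round(cmp$case_case_meta$q_stat, 2), 5.38)
  expect_equal(cmp$case_case_meta$df, 3)
  expect_equal(cmp$case_case_meta$i_squared, 44.3, tolerance = 0.005)
  expect_gt(cmp$case_case_meta$p_het, 0.1)
})

test_that("identical subtype distributions pool to a null comparison", {
  df <- data.frame(
    study_id = rep(c("s1", "s2"), each = 2),
    year = 2020L, ethnicity = "x",
    phenotype = rep(c("neovascular_amd", "pcv"), 2),
    n_gg = c(30, 30, 50, 50), n_gt = c(40, 40, 60, 60),
    n_tt = c(30, 30, 20, 20)
  )
  cmp <- compare_subtypes(as_snp_dataset(df))
  expect_equal(cmp$freq_diff, 0, tolerance = 1e-12)
  expect_equal(cmp$case_case_meta$q_stat, 0, tolerance = 1e-12)
  expect_equal(cmp$case_case_meta$summary_or, 1, tolerance = 1e-12)
  ## no dual-subtype study -> error
  expect_error(compare_subtypes(as_snp_dataset(df[c(1, 4), ])), "no study")
})
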