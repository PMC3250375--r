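test_that("allelic ORs of the new cohort match the published values", {
  res <- allelic_or(new_cohort$namd, new_cohort$control)
  expect_equal(round(res$estimate, 2), 2.82)
  expect_equal(round(res$ci_low, 2), 2.10)
  expect_equal(round(res$ci_high, 2), 3.78)
  expect_equal(res$p_value, 2.4e-12, tolerance = 0.05)
  expect_false(res$continuity_corrected)

  res <- allelic_or(new_cohort$pcv, new_cohort$control)
  expect_equal(round(res$estimate, 2), 2.39)
  expect_equal(round(res$ci_low, 2), 1.80)
  expect_equal(round(res$ci_high, 2), 3.17)
  expect_equal(res$p_value, 1.3e-9, tolerance = 0.05)
})

test_that("identical case and control groups give OR = 1, p = 1", {
  g <- genotype_counts(20, 30, 10)
  res <- allelic_or(g, g)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  gt <- genotype_specific_ors(g, g)
  expect_equal(gt$gt_vs_gg$estimate, 1, tolerance = 1e-12)
  expect_equal(gt$tt_vs_gg$estimate, 1, tolerance = 1e-12)
})

test_that("allelic_or is antisymmetric under case/control swap", {
  set.seed(11)
  for (i in 1:20) {
    pair <- random_genotype_pair()
    ab <- allelic_or(pair$case, pair$control)
    ba <- allelic_or(pair$control, pair$case)
    expect_equal(ab$estimate, 1 / ba$estimate, tolerance = 1e-12)
    expect_equal(ab$ci_low, 1 / ba$ci_high, tolerance = 1e-12)
    expect_equal(ab$ci_high, 1 / ba$ci_low, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("Woolf CI brackets the estimate and tightens with sample size", {
  set.seed(13)
  for (i in 1:20) {
    pair <- random_genotype_pair()
    res <- allelic_or(pair$case, pair$control)
    expect_lte(res$ci_low, res$estimate)
    expect_gte(res$ci_high, res$estimate)
    scaled <- allelic_or(genotype_counts(4 * pair$case[1], 4 * pair$case[2],
                                         4 * pair$case[3]),
                         genotype_counts(4 * pair$control[1],
                                         4 * pair$control[2],
                                         4 * pair$control[3]))
    expect_equal(scaled$estimate, res$estimate, tolerance = 1e-12)
    expect_lt(scaled$ci_high / scaled$ci_low, res$ci_high / res$ci_low)
  }
})

test_that("genotype-specific ORs reproduce the published point estimates", {
  res <- genotype_specific_ors(new_cohort$namd, new_cohort$control)
  expect_equal(round(res$gt_vs_gg$estimate, 2), 2.62)
  expect_equal(round(res$tt_vs_gg$estimate, 2), 7.49)
  ## PCV: crude cross-tab values (direct 2x2 arithmetic as oracle)
  res <- genotype_specific_ors(new_cohort$pcv, new_cohort$control)
  expect_equal(res$gt_vs_gg$estimate, (77 * 79) / (42 * 94), tolerance = 1e-12)
  expect_equal(res$tt_vs_gg$estimate, (79 * 79) / (42 * 30), tolerance = 1e-12)
})

test_that("cross-tab genotype ORs equal the maximum-likelihood logistic fit", {
  res <- genotype_specific_ors(new_cohort$namd, new_cohort$control)
  oracle <- glm_genotype_ors(new_cohort$namd, new_cohort$control)
  expect_equal(res$gt_vs_gg$estimate, unname(oracle["genogt"]),
               tolerance = 1e-6)
  expect_equal(res$tt_vs_gg$estimate, unname(oracle["genott"]),
               tolerance = 1e-6)
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  res <- allelic_or(genotype_counts(10, 0, 0), genotype_counts(5, 10, 5))
  expect_true(res$continuity_corrected)
  expect_true(is.finite(res$log_or) && res$estimate > 0)
  res <- genotype_specific_ors(genotype_counts(10, 0, 5),
                               genotype_counts(5, 10, 5))
  expect_true(res$gt_vs_gg$continuity_corrected)
  expect_false(res$tt_vs_gg$continuity_corrected)
  expect_error(allelic_or(genotype_counts(0, 0, 0), new_cohort$control),
               "zero subjects")
})
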