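## Shared fixtures and independent oracles for the test suite.

table2_path <- function() {
  system.file("extdata", "table2.csv", package = "snpmeta")
}

table2_dataset <- function() read_dataset(table2_path())

## Genotype counts of the newly genotyped cohort (the "this_study" rows).
new_cohort <- list(
  namd = genotype_counts(26, 81, 74),
  pcv = genotype_counts(42, 77, 79),
  control = genotype_counts(79, 94, 30)
)

## Independent brute-force oracle for the exact HWE test: enumerate every
## genotype configuration compatible with the observed allele counts and sum
## the conditional probabilities (factorial formula) of all configurations no
## more probable than the observed one. Deliberately naive; no log-space
## tricks.
hwe_oracle <- function(gg, gt, tt) {
  n <- gg + gt + tt
  n_t <- gt + 2 * tt
  n_g <- 2 * gg + gt
  if (n_t == 0 || n_g == 0) return(1)
  rare <- min(n_t, n_g)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    factorial(n) / (factorial(hom_rare) * factorial(h) *
                      factorial(hom_common)) * 2^h *
      factorial(n_t) * factorial(n_g) / factorial(2 * n)
  }, numeric(1))
  p_obs <- prob[hets == gt]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

## Random genotype-count tables with all cells positive (no continuity
## correction in play), for logistic/cross-tab equivalence checks.
random_genotype_pair <- function() {
  list(case = genotype_counts(sample(5:60, 1), sample(5:60, 1),
                              sample(5:60, 1)),
       control = genotype_counts(sample(5:60, 1), sample(5:60, 1),
                                 sample(5:60, 1)))
}

## Logistic-regression oracle for genotype-specific ORs: saturated
## categorical fit of case status on genotype via glm (IRLS maximum
## likelihood), returning the GT-vs-GG and TT-vs-GG odds ratios.
glm_genotype_ors <- function(case, control) {
  d <- data.frame(
    status = rep(c(1, 0), each = 3),
    geno = factor(rep(c("gg", "gt", "tt"), 2), levels = c("gg", "gt", "tt")),
    count = c(as.integer(case), as.integer(control))
  )
  fit <- stats::glm(status ~ geno, family = stats::binomial(), data = d,
                    weights = count)
  exp(stats::coef(fit)[c("genogt", "genott")])
}
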