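---
title: "Methods: case-control SNP meta-analysis with disease-subtype comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP meta-analysis with disease-subtype comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A biallelic SNP is genotyped in cases and controls across several studies,
and each study reports only the aggregate genotype counts GG/GT/TT per
group. The scientific questions this package answers from such tables are:

1. Is the risk allele T associated with disease in each study and overall?
2. How large is the pooled effect, and is it consistent across studies?
3. What fraction of cases in the population is attributable to the allele?
4. Does the allele's effect differ between two subtypes of the disease?

The motivating application is the *ARMS2* A69S variant (rs10490924) in the
two neovascular macular disease subtypes — neovascular age-related macular
degeneration (AMD) and polypoidal choroidal vasculopathy (PCV) — in Asian
populations, and the packaged dataset (`inst/extdata/table2.csv`, six
studies, 3,828 subjects) is that literature's complete count table. All of
the numbers quoted below are computed by this package's test suite and
acceptance script from that table; nothing is transcribed by hand.

## Data model and conventions

A dataset is a CSV with one row per (study, phenotype group) and the closed
phenotype vocabulary `neovascular_amd`, `pcv`, `control`. The genotype
column order fixes the risk-allele orientation: the third count is
homozygous for the risk allele, so every odds ratio is relative to the major
allele G. Validation (non-negative counts, no duplicate study/phenotype
pairs, known labels) happens at read time; an empty table is legal until a
pooling operation needs at least one study.

All confidence intervals are normal-theory 95% intervals (multiplier 1.96)
on the log-OR or proportion scale. This is deliberately not configurable:
the package targets the reporting conventions of the genetic-epidemiology
literature it serves.

## Per-study association

**Allelic (allele-contrast) OR.** Genotype counts collapse to allele counts
(2n alleles per group); the OR and its Woolf standard error
$\sqrt{\sum 1/\text{cell}}$ come from the 2×2 allele table, and the p-value
is the Pearson chi-square on that table (1 df, two-sided, no Yates
correction — plain Pearson reproduces the published association p-values
such as 2.4 × 10⁻¹²). Treating alleles as independent observations is the
standard allele-contrast model; it is exact under Hardy–Weinberg equilibrium
(HWE) in each group and is why the HWE check below matters.

**Zero cells.** If any cell of a 2×2 table is zero the package adds 0.5 to
all four cells of that table only (Haldane–Anscombe) and flags the result.
The packaged data contain no zero cells; the rule exists for small simulated
or user-supplied tables.

**Genotype-specific ORs.** GT-vs-GG and TT-vs-GG contrasts with GG as the
baseline. With a single categorical predictor and no covariates, the
maximum-likelihood logistic-regression estimates equal the cross-tabulation
ORs, so the implementation is the cross-tab with Woolf CIs; the test suite
asserts equality with a `glm` fit to 10⁻⁶ relative error on random tables.
On the packaged cohort this reproduces the published neovascular AMD point
estimates 2.62 and 7.49 exactly. Two published values it deliberately does
not reproduce: the source study's PCV genotype ORs (printed 1.56 and 5.02)
differ slightly from the crude cross-tab values implied by its own counts
(1.54 and 4.95, presumably an unstated adjustment), and its published CIs
for the genotype ORs are a little wider than Woolf/Wald intervals
(profile-likelihood intervals from a different software stack would behave
this way). The package reports its own documented definitions rather than
chasing unexplained discrepancies.

**Exact HWE test.** Conditional on the observed allele counts, the
heterozygote count under HWE has a hypergeometric-form distribution over all
counts of matching parity; the two-sided p-value sums the probabilities of
every configuration no more probable than the observed one (the canonical
definition, not the mid-p variant, which is what reproduces the published
control-group p-values 0.10/0.51/1.0/0.82/0.70/0.88). Probabilities are
computed in log space and normalised, so samples of 10⁵ subjects are no
problem; a monomorphic sample returns p = 1 by convention. The test suite
checks the implementation against a naive full-enumeration oracle for every
genotype triple with n ≤ 25.

## Meta-analysis

**Fixed effects.** The Mantel–Haenszel estimator pools the per-study allele
tables; the variance of the log pooled OR is the Robins–Breslow–Greenland
estimator, the de-facto standard that is consistent under both many-small-
strata and few-large-strata asymptotics. On the packaged data this gives
3.09 (2.71–3.51) for neovascular AMD (4 studies) and 2.13 (1.91–2.38) for
PCV (6 studies), and is cross-checked against `metafor::rma.mh` in the
tests.

**Heterogeneity.** Cochran's Q is computed on the per-study Woolf log-ORs
with inverse-variance weights about the inverse-variance mean — the standard
Cochran definition, chosen over centring on the MH estimate because only the
p < 0.1 decision rule is load-bearing downstream. I² = max(0, (Q − df)/Q),
floored at zero and reported as a percentage.

**Random effects.** DerSimonian–Laird: τ² by the method of moments from Q,
floored at zero, then inverse-variance pooling with weights 1/(vᵢ + τ²).
When Q ≤ df this collapses exactly to the inverse-variance fixed-effects
estimate (asserted to 10⁻¹² in the tests). Both models are always fitted
(given ≥ 2 studies); under the default `model = "auto"` rule the reported
model is random effects only when the Q-test p-value is below 0.1. On the
packaged data no analysis crosses that threshold, so every reported summary
is fixed-effects — matching the source study's model-selection narrative.

**Pooled proportions.** Control risk-allele and carrier frequencies are
pooled on the *raw* proportion scale with inverse-variance weights
(variance pᵢ(1−pᵢ)/nᵢ), CI $\bar p \pm 1.96/\sqrt{\sum w_i}$. The raw scale
rather than logit is a deliberate choice: it is the scheme that exactly
reproduces the published pooled estimates and heterogeneity statistics
(37.4% [35.9–38.8], Q = 8.50, I² = 41.2% for alleles; 60.8% [58.7–62.9],
Q = 9.0, I² = 44.5% for carriers) from the counts, which pins down the
convention the field's tooling used. A degenerate study proportion of 0
or 1 has zero estimated variance, so its weight is computed from the shrunk
proportion (s + 0.5)/(n + 1) and the result is flagged.

## Population attributable risk

Levin's formula, PAR = p(OR − 1)/(1 + p(OR − 1)), with the pooled control
risk-allele frequency as the exposure prevalence p and the pooled summary OR
per subtype; CI bounds substitute the OR's CI bounds. Among the candidate
attributable-risk definitions (Levin population-based vs Miettinen
case-based; allele vs carrier prevalence) this is the combination that
reproduces all six published PAR numbers, so it is fixed, not an option. A
protective OR < 1 yields a negative PAR, returned as-is with a flag rather
than clamped — truncation would hide a sign error in the caller's
orientation.

One rounding subtlety: computed at full precision the neovascular AMD PAR is
43.8%, while feeding Levin's formula the summary OR and frequency *at their
reported precision* (3.09, 0.374) gives 43.9% — evidently how the original
figure was produced. The pipeline never re-rounds intermediates, so its
report prints 43.8%; the tests assert both facts explicitly.

## Subtype comparison

Restricted to studies containing both case subtypes (four of the six):

- **Pooled case frequencies** per subtype, pooled as above (64.7% vs
  55.6%), compared with a two-sided z-test on the difference using the
  pooled standard errors (p ≈ 10⁻⁷, reported as p < 0.001). A z-test on the
  pooled estimates, not a chi-square on summed raw counts, keeps the test
  consistent with the pooling model.
- **Case-case OR meta-analysis**: per-study allele-contrast ORs of subtype
  A vs subtype B with Woolf variances, pooled by inverse variance (no
  control stratum exists, so MH weighting does not apply). This
  reproduces Q = 5.38, df = 3, I² = 44.2% on the packaged data. The
  algebraic identity OR(A vs B) = OR(A vs ctrl)/OR(B vs ctrl) on crude
  cross-tabs is asserted in the tests.
- **Case-only logistic test** per study: subtype indicator regressed on
  genotype. The default coding is additive dose (0/1/2 risk alleles, Wald
  z-test), the natural companion of the multiplicative allelic model; a
  genotypic coding (two indicators, 2-df likelihood-ratio test) is provided
  for sensitivity analysis. On the new cohort the additive test gives
  p = 0.297; the source study printed 0.31 without stating its coding, and
  no coding we examined (additive 0.297, genotypic 0.19, carrier 0.08)
  lands exactly on 0.31, so this value is documented but not treated as a
  reproduction target. Maximum likelihood is by iteratively reweighted
  least squares on the aggregated six-cell table; complete separation is
  detected (diverging coefficient or standard error) and flagged, with the
  p-value reported as missing rather than a misleading Wald value.

## The simulator

`simulation_scenario()` / `simulate_dataset()` generate multi-study count
tables with exactly the structure the estimators assume: control genotypes
multinomial under HWE at the study's control allele frequency; the case
allele frequency derived from the subtype's true allelic OR on the
per-allele odds scale, with case genotypes again in HWE (so the implied
genotype ORs follow the multiplicative pattern OR_TT ≈ OR_allelic²,
matching the observed 2.62/7.49-style gradient); optional log-normal
between-study spread τ on the log OR; optional heterozygote-deficit
perturbation (inbreeding coefficient 0.1) of the controls for exercising
the HWE test's power.

The default scenario is the packaged design itself: six studies, control
allele frequencies 0.33–0.39, subtype ORs 3.09 and 2.13, the real per-group
sample sizes, and two studies without a neovascular AMD arm. Randomness is
consumed through per-study sub-streams derived deterministically from the
global seed, so a fixed seed is byte-reproducible and appending a study
never perturbs earlier studies' draws.

What the simulator does *not* emulate — and hence what passing calibration
tests do not certify about real data: population stratification, linkage
disequilibrium with neighbouring variants, genotyping error, HWE departures
in cases beyond the multiplicative model, and covariate structure (age,
sex). It validates the estimators' statistical calibration, not the
genotyping pipeline upstream of the count table.

## Calibration results the test suite computes

On the default scenario, the Mantel–Haenszel 95% CI covers the generating
ORs at 0.944–0.948 over 2,000 replicates (nominal 0.95 ± 0.02 band); the
case-only additive test's type-I error under equal subtype ORs is 0.052
over 5,000 replicates; the exact HWE test rejects true-HWE controls at
0.046 (conservative, ≤ nominal) over 5,000 replicates; and DerSimonian–
Laird recovers τ² = 0.09 within two Monte-Carlo standard errors over 500
replicates of a five-study design with true log-OR spread τ = 0.3. These
replicate counts keep the whole suite near one minute on a single CPU while
leaving Monte-Carlo error well inside the asserted bands.

## Numerical and degenerate-input choices

- All 2×2 arithmetic is done in double precision after explicit coercion
  (allele counts of 10⁵-subject groups overflow 32-bit integers).
- HWE enumeration works on normalised log-probabilities; the "≤ observed
  probability" comparison uses a 1 + 10⁻¹² relative tolerance so that exact
  ties are included regardless of floating-point noise.
- Empty case or control groups, all-zero margins, and an empty dataset all
  raise immediate, named errors rather than propagating NaN.
- `run_full_analysis()` wraps each stage with its name; `keep_going = TRUE`
  degrades to a partial report with the failed stages recorded as `NULL`.

## Limitations

- No covariate adjustment: the estimators operate on aggregate counts, so
  confounders cannot be modelled; this matches the primary analyses of the
  literature the package reproduces.
- No publication-bias diagnostics (funnel plots, Egger, trim-and-fill) and
  no meta-regression.
- Biallelic autosomal variants only; no X-linked or multi-allelic handling.
- The case-only test assumes both subtype samples arise from the same
  source population; across-study case-only pooling is deliberately not
  offered (the case-case OR meta-analysis covers that use).
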