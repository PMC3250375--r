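# snpmeta

Case-control SNP association and meta-analysis with disease-subtype
comparison, from aggregate genotype counts.

## What it is for

Association studies of a biallelic SNP are usually published as a table of
genotype counts (GG/GT/TT) per phenotype group. `snpmeta` implements the
complete statistical workflow that such tables support, aimed at
ophthalmic-genetics and genetic-epidemiology analysts comparing the
hereditary contribution of a risk variant between disease subtypes — the
motivating case being the *ARMS2* A69S variant (rs10490924) in neovascular
age-related macular degeneration (AMD) versus polypoidal choroidal
vasculopathy (PCV):

- **Per-study association.** Allele-contrast odds ratios
  OR = (T_case · G_ctrl)/(G_case · T_ctrl) with Woolf standard errors
  √(Σ 1/cell) and Pearson chi-square p-values; genotype-specific ORs (GT vs
  GG, TT vs GG), equal to the saturated logistic-regression estimates;
  exact Hardy–Weinberg tests by conditional enumeration of heterozygote
  counts.
- **Meta-analysis.** Mantel–Haenszel fixed-effects pooling,
  OR_MH = Σ aᵢdᵢ/nᵢ / Σ bᵢcᵢ/nᵢ, with the Robins–Breslow–Greenland
  variance; DerSimonian–Laird random effects with
  τ² = max(0, (Q − df)/(Σw − Σw²/Σw)); Cochran's Q and I² heterogeneity
  with the fixed-vs-random choice at the conventional p < 0.1 rule.
- **Pooled frequencies.** Inverse-variance fixed-effects pooling of
  risk-allele and carrier (GT+TT) frequencies across control groups, with
  Q and I².
- **Attributable risk.** Levin's formula PAR = p(OR−1)/(1 + p(OR−1)) with
  the pooled control allele frequency as exposure prevalence; CI by
  substituting the OR's CI bounds.
- **Subtype heterogeneity.** Case-case allele-contrast ORs with
  inverse-variance pooling, a z-test of the difference in pooled subtype
  allele frequencies, and the single-study case-only logistic test
  (subtype on genotype dose).
- **Simulation.** A multinomial genotype-count generator under
  Hardy–Weinberg proportions with per-subtype allelic ORs, used by the test
  suite to verify CI coverage and type-I error calibration.

The package ships the complete six-study Asian A69S dataset (3,828
subjects) as `inst/extdata/table2.csv`.

## Worked example

```r
library(snpmeta)
ds <- read_dataset(system.file("extdata", "table2.csv", package = "snpmeta"))

fit <- snp_meta(ds, "neovascular_amd")
summary(fit)
#> Allele-contrast meta-analysis: neovascular_amd vs control
#>
#>    study_id   or        ci p_value weight
#>  study_2009 4.16 2.89-5.99 3.6e-15  10.6%
#>  study_2010 2.87 2.44-3.38 3.1e-38  63.8%
#>  study_2011 4.39 2.69-7.17 8.1e-10   5.7%
#>  this_study 2.82 2.10-3.78 2.4e-12  19.9%
#>
#> Fixed effects (Mantel-Haenszel):
#>   Pooled OR [mantel_haenszel_fixed, k=4] = 3.09 (95% CI 2.71-3.51), p = 1.55e-66
#> Heterogeneity: Q = 5.66, df = 3, p = 0.129, I2 = 47.0%
#> Random effects (DerSimonian-Laird):
#>   Pooled OR [dersimonian_laird_random, k=4] = 3.26 (95% CI 2.65-4.00), p = 2.49e-29
#> Heterogeneity: Q = 5.66, df = 3, p = 0.129, I2 = 47.0%, tau2 = 0.0202
#> Model selected: mantel_haenszel_fixed
```

The risk allele is carried at a pooled frequency of 37.4% in controls; the
pooled OR of 3.09 means a T allele roughly triples the odds of neovascular
AMD, and no between-study heterogeneity is declared (Q-test p = 0.13 ≥ 0.1),
so the fixed-effects model is reported.

```r
ctl <- lapply(study_ids(ds), function(s) study_group(ds, s, "control"))
al  <- vapply(ctl, allele_counts, numeric(2))
freq <- pooled_proportion(al["t", ], colSums(al), "allele")
freq
#> Pooled allele frequency = 37.4% (95% CI 35.9-38.8)
#> Heterogeneity: Q = 8.50, df = 5, p = 0.131, I2 = 41.2%

par_levin(fit, freq)
#> Population attributable risk = 43.8% (95% CI 39.0%-48.4%)  [exposure frequency 0.374]

compare_subtypes(ds)
#> Subtype comparison: neovascular_amd (A) vs pcv (B), 4 dual-subtype studies
#> Pooled risk-allele frequency: 64.7% vs 55.6% (diff p = 1.1e-07)
#> Case-case allele contrast:
#>   Pooled OR [inverse_variance_fixed, k=4] = 1.46 (95% CI 1.26-1.68), p = 2.29e-07
#> Heterogeneity: Q = 5.38, df = 3, p = 0.146, I2 = 44.2%
```

About 44% of neovascular AMD cases in this population are attributable to
the risk allele, versus 29.7% of PCV cases; the case-case contrast (pooled
OR 1.46, p ≈ 2 × 10⁻⁷) shows the variant's effect is significantly stronger
in neovascular AMD than in PCV. `run_full_analysis(ds)` chains every stage
and prints the whole report; `plot(fit)` draws the forest plot.

## Documentation

The methods vignette (`vignettes/subtype-meta-analysis.Rmd`) describes the
statistical models, the estimator choices and their assumptions, the
simulation design, and known limitations.
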