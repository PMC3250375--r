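Package: snpmeta
Title: Case-Control SNP Association and Meta-Analysis with Disease-Subtype
    Comparison
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical toolkit for biallelic SNP case-control association
    studies and their cross-study synthesis. Computes per-study allelic and
    genotype-specific odds ratios with Woolf confidence intervals, exact
    Hardy-Weinberg equilibrium tests, Mantel-Haenszel fixed-effects and
    DerSimonian-Laird random-effects pooled odds ratios with Cochran's Q and
    I-squared heterogeneity statistics, fixed-effects pooling of allele and
    carrier frequencies, population attributable risk via Levin's formula,
    and case-only logistic tests of genetic-effect heterogeneity between
    disease subtypes. Includes a multinomial genotype-count simulator under
    Hardy-Weinberg proportions for calibration studies, and an end-to-end
    analysis report with forest plots.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    metafor,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
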