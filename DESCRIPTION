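Package: lipidsem
Title: Path Analysis of Direct and Indirect SNP Effects on Longitudinal
    Triglycerides Through HDL and CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Observed-variable structural equation (path) models for
    dissecting how a triglyceride-associated SNP acts on triglycerides at a
    final study visit: directly, through earlier triglyceride measurements,
    through longitudinal HDL cholesterol, and through methylation at nearby
    CpG sites. Provides maximum-likelihood estimation of recursive linear
    systems with family-clustered Huber-White sandwich covariance,
    chi-square/RMSEA/CFI/TLI model-fit gating, p-value based CpG pruning,
    delta-method indirect (product-of-coefficients) pathway effects with
    directional-consistency filtering and Bonferroni summaries, methylation
    principal-component adjustment and SNP-window CpG selection, and a
    calibrated generator of synthetic family cohorts (pedigrees, Mendelian
    genotypes, CpG beta values, lognormal longitudinal lipids with a
    fenofibrate mean/variance shift between visits 2 and 3).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
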