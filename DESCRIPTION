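Package: twinlipids
Title: Heritability and Omics Association Analysis of the Plasma Lipidome in Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of plasma lipid species measured in
    monozygotic and dizygotic twin pairs. Implements maximum-likelihood twin
    structural equation models (ACE, AE, CE, E) with profile-likelihood
    confidence intervals and likelihood-ratio tests of heritability, bivariate
    Cholesky models for genetic and environmental correlations, sex-heterogeneity
    and age-moderation (gene-by-environment) models, lipidomics quality control
    (internal-standard normalization, coefficient-of-variation and peak-quality
    filters, duplicate resolution, class group sums, shorthand nomenclature
    parsing), covariate residualization with rank-based inverse normal
    transformation, pair-clustered mixed-model association of lipids with gene
    expression probes, lasso probe selection with likelihood-based pseudo
    r-squared, genome-wide average methylation (GWAM) association, and summary
    reporting. Ships a seeded synthetic twin-cohort generator with known ground
    truth so the whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
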