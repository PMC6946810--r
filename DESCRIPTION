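Package: pulmomr
Title: Two-Sample Mendelian Randomization of Pulmonary Function and Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-sample Mendelian randomization
    (MR) studies of continuous exposures (such as spirometry-derived pulmonary
    function) on binary disease outcomes. Provides synthetic-data generators
    with known ground truth (genotype panels with block linkage disequilibrium,
    phenotypes, spirometry blow series, and paired exposure/outcome GWAS summary
    statistics); spirometry quality control and phenotype derivation; per-variant
    association scans with two-stage instrument selection and LD clumping;
    harmonization of exposure and outcome summary statistics including
    palindromic-variant handling and LD proxies; five causal-effect estimators
    (Wald ratio, inverse-variance weighted with multiplicative random effects,
    maximum likelihood, weighted median, and a robust adjusted profile score)
    plus multivariable MR; heterogeneity, pleiotropy, directionality and power
    diagnostics; and LD-score-regression heritability, genetic correlation, and
    partitioned heritability at synthetic scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
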