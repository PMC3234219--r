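Package: regulaburden
Title: Function-Informed Rare-Variant Burden Testing for Regulatory Regions
Version: 0.1.0
Authors@R:
    person("regulaburden", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Collapsing (burden) association analysis for rare regulatory
    variants discovered by resequencing phenotypic extremes of a continuous
    trait. Implements the cohort allelic sums test (CAST) and its
    function-informed refinements: direction-stratified collapsing using
    dual-luciferase reporter assay calls, and an exclusivity filter that
    restricts to variants private to one phenotypic extreme. Supporting
    stages include reporter-plate normalization and direction calling,
    two-locus EM haplotype-frequency estimation with D, D' and r2,
    quantitative-trait residualization and additive genotype regression,
    frequency-weighted sum and C-alpha comparator tests, and a synthetic
    extreme-phenotype cohort generator for power and type-I-error studies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
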