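Package: mapgs
Title: Multi-Ancestry, Multi-Trait Polygenic Score Construction and Evaluation
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds genome-wide polygenic scores from ancestry-stratified GWAS
    summary statistics by Bayesian spike-and-slab shrinkage of marginal effect
    sizes over block linkage-disequilibrium reference panels, combines the
    resulting candidate scores in a two-layer scheme (logistic mixing of
    ancestry-specific scores within a trait, then of trait-level scores), and
    evaluates the combined score with the standard clinical battery:
    odds/hazard ratios per standard deviation, Nagelkerke and liability-scale
    R-squared, Harrell's C, net reclassification improvement, percentile and
    tail-of-distribution analyses, and an integrated clinical-by-genetic Cox
    model. A synthetic-cohort module simulates block-LD genotypes, correlated
    multi-trait effects, liability-threshold disease and incident event times
    so the full pipeline is testable without access to restricted biobank
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
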