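Package: mica
Title: Microbiome Co-Occurrence Analysis of Effect Modification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage Microbiome Co-occurrence Analysis (MiCA) of effect
    modification. Stage one discovers microbial cliques -- small sets of
    co-occurring taxa jointly predictive of an outcome -- with a repeated
    holdout signed iterative random forest (rh-SiRF) that parses signed
    decision paths, mines frequent signed itemsets, scores their stability
    over random train/test partitions, and selects combinations forming a
    closed-loop co-occurrence network. Stage two turns each clique into an
    integer presence indicator and estimates stratified covariate-adjusted
    associations with permutation p-values, cross-stratum validation, a
    single-model interaction test, and propensity-subclassification balance
    diagnostics. Includes compositional preprocessing (relative abundance,
    prevalence filtering, quartile coding, Shannon diversity, predictive
    mean matching imputation), per-taxon screening with FDR correction, and
    a seeded synthetic-cohort generator with planted cliques and
    modifier-specific effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    data.table,
    jsonlite,
    yaml,
    withr,
    vegan,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
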