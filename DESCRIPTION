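Package: genestack
Title: Gene-Based Association Tests from Stacked Ensemble Phenotype Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-marker (gene-based) association testing built on
    cross-validated phenotype predictions from a stacked ensemble of
    machine-learning models (linear or logistic regression, linear-kernel
    support vector machine, and random forests blended by a meta-level
    random forest). Provides joint association tests for quantitative and
    case-control traits, covariate-adjusted tests via the Steiger Z test
    for dependent correlations, and a nested-model test for epistatic
    interactions, together with classical comparison tests (Fisher
    combination, Simes, GATES, VEGAS, and regression gene tests), a
    genotype/phenotype simulator with Hardy-Weinberg genotypes, block
    linkage disequilibrium and penetrance or epistatic trait models, and a
    Monte-Carlo engine for Type-I error and power estimation with exact
    binomial confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    ranger,
    e1071,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
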