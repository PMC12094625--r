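Package: famliab
Title: Liability-Threshold Common-Factor Models for Twin and Sibling Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate variance-component modelling of binary lifetime
    diagnoses in genetically informative relative pairs. Implements the
    liability-threshold common-pathway (common factor) A/C/E model for four
    disorders observed in five relative classes (monozygotic and dizygotic
    twins, full siblings, and half-siblings reared together or apart),
    maximum-likelihood fitting via composite pairwise or full-pattern
    likelihoods with AIC model comparison and bootstrap confidence
    intervals, bivariate correlated-factors ACE models for genetic
    correlations, tetrachoric correlation descriptives with standard
    errors, and a seeded synthetic-data generator emulating the registry
    pair design so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mvtnorm,
    numDeriv,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
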