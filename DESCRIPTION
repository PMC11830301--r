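Package: famliab
Title: Familial Aggregation and Liability-Scale Genetic Models for Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic epidemiology of rare psychiatric phenotypes in
    population registers, exercised end-to-end on a synthetic registry generator
    with known ground truth. Implements a pedigree-structured liability-threshold
    simulator (configurable additive genetic, shared and unique environment
    variance shares, cross-trait genetic correlations, mutually exclusive
    diagnosis assignment, diagnosis dates and polygenic score columns); ICD-based
    phenotype definitions and relative-pair extraction; familial aggregation and
    coaggregation odds ratios from logistic models with family-clustered sandwich
    standard errors; tetrachoric correlations, weighted-least-squares ACE/AE
    heritability from full-sibling versus cousin contrasts, maximum-likelihood
    genetic correlations for ordinary and mutually exclusive trait pairs with
    family bootstrap confidence intervals; case-case polygenic-score logistic
    models; and fixed-effect inverse-variance meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
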