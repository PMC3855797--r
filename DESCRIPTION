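Package: twinglyco
Title: Twin-Based Variance Decomposition and Epigenome-Wide Association
    for IgG Glycan Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genetic and environmental control of
    immunoglobulin G (IgG) N-glycosylation in classical twin designs. Simulates
    twin cohorts with known additive-genetic (A), shared-environment (C) and
    unique-environment (E) variance structure, UPLC glycan peak compositions and
    methylation matrices with planted effects; computes derived glycan traits
    from a 24-peak table via an annotation-driven grammar; fits ACE/AE/CE/E
    variance-component models by maximum likelihood with likelihood-ratio and
    AIC model selection, profile-likelihood confidence intervals, intra-class
    correlations and simulation-based power; runs family random-intercept
    epigenome-wide association scans with Bonferroni control; and tests
    enrichment of array-wide hits across heritability classes with exact
    hypergeometric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
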