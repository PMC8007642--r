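Package: mrmediate
Title: Two-Sample and Multivariable Mendelian Randomisation with
    Mediation Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-statistics Mendelian randomisation for a continuous
    exposure and a binary outcome, built around the analysis of physical
    activity and colorectal cancer risk with adiposity mediation.  Reads
    and harmonises GWAS summary statistics, builds genetic instruments
    (p-value thresholding, LD pruning, variance explained and F
    statistics), fits the inverse-variance-weighted, MR-Egger, weighted
    median, mode-based and robust estimators with heterogeneity and
    pleiotropy diagnostics (Cochran's Q, Egger intercept, MR-PRESSO,
    leave-one-out), estimates direct effects by multivariable MR,
    decomposes total effects into direct and mediated components with
    Monte-Carlo uncertainty intervals, and computes non-centrality-based
    power.  A seeded synthetic summary-statistics generator with known
    causal structure (direct and mediated paths, pleiotropy, LD, sample
    overlap) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
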