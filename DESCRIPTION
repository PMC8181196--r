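Package: lncsubtype
Title: Expression Subtype Discovery and Bayesian Compound Covariate
    Classification for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for long non-coding RNA (lncRNA) based
    molecular subtyping of tumor expression cohorts: unsupervised subtype
    discovery by hierarchical clustering, one-vs-rest t-test gene
    signatures ranked by log ratio, a Bayesian compound covariate
    predictor (BCCP) that assigns per-sample subtype posterior
    probabilities, Kaplan-Meier / log-rank survival association including
    within-subtype treatment benefit, cross-tabulation against
    alternative subtype systems, pre-ranked gene set enrichment, and
    Spearman screening of drug-sensitivity panels against subtype
    probability. A synthetic-cohort generator emulates the data
    structures the analyses assume so the whole chain is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    optparse
Config/testthat/edition: 3
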