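Package: netstrat
Title: Network-Based Stratification of Tumor Cohorts from Co-Expression Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted gene co-expression networks on a reference
    cohort, discovers and validates modules (topological overlap,
    dynamic branch cutting, eigengenes, kME, stability and
    topological-significance gates), projects new cohorts onto the
    reference module axes after reference-batch harmonization, distills
    modules into portable gene signatures scored by single-sample
    enrichment, learns one-dimensional threshold classifiers of
    treatment response, calls nearest-centroid molecular subtypes with
    an indeterminate margin and a response-based rescue rule,
    decomposes modules into patient-specific networks by linear
    interpolation against the reference with wiring statistics, tests
    expression and network features between groups, and summarizes
    immune-repertoire clonotype diversity. Ships a synthetic-cohort
    generator with planted modules and known response structure so the
    whole pipeline is testable without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    mclust,
    vegan
Config/testthat/edition: 3
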