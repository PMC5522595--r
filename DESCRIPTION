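Package: panelkit
Title: Design and Evaluation of SNP Marker Panels for Conservation Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate reduced SNP marker panels for the
    genetic monitoring of small, structured wildlife populations. Covers
    genotype quality control and replicate-based error-rate bounding,
    Mendelian-inconsistency screening of pedigreed samples with X-linkage
    flagging, per-pool population-genetic filtering (Hardy-Weinberg tests,
    linkage-disequilibrium pruning, Weir-Cockerham differentiation),
    per-locus informativeness statistics for individual identification,
    parentage exclusion and relatedness inference (probability of identity,
    exclusion probabilities, relatedness informativeness, likelihood-ratio
    power), nested panel ranking, and simulation plus Bayesian (Gibbs)
    classification of admixed ancestry categories. A seeded synthetic-data
    generator emulating two diverged genetic pools makes the whole pipeline
    runnable and testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
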