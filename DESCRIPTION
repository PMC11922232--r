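Package: hlner
Title: Lexicon-Based Named Entity Recognition for Hodgkin Lymphoma Social Media Posts
Version: 0.1.0
Authors@R:
    person("hlner", "maintainers", email = "hlner@example.org", role = c("aut", "cre"))
Description: A schema-configurable pipeline for characterizing Hodgkin lymphoma
    disease and treatment concepts in short social-media posts. Provides a
    nine-class concept lexicon (classes, attributes, surface forms, inclusion /
    exclusion / false-positive term lists), tweet-style text normalization with
    inclusion-exclusion query filtering and namesake false-positive removal,
    approximate dictionary matching under optimal-string-alignment
    Damerau-Levenshtein distance, a post-level evaluation harness (sensitivity,
    specificity, precision, NPV, FPR, FDR, FNR, accuracy, F1, and Cohen's
    kappa), frequency reporting with stage-grouping rules, and a seeded
    synthetic-corpus generator so every stage is testable without any external
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
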