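Package: fluencer
Title: Automated Cluster Analysis of Verbal Fluency Task Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated analysis of semantic and phonematic
    verbal fluency task (VFT) transcripts. Implements traditional
    clustering of word sequences (thematic list-based clustering for
    semantic fluency, Troyer-style phonematic rules for letter fluency),
    an embedding-based semantic-relatedness clustering method with fixed
    cosine thresholds, including in-package skip-gram/CBOW training with
    negative sampling, transcript quality control (violation marking,
    exclusion rules), word-level error-rate measurement for automatic
    speech recognition output, cluster characteristics (total word count,
    mean cluster size, switches, mean sequential relatedness),
    hyperparameter grid search supervised by category lexicons, and the
    association statistics used to relate cluster characteristics to
    neuropsychological scores, with network-graph edge export. Synthetic
    data generators (toy corpora with theme structure, transcripts with
    planted clusters, ASR corruption) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
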