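Package: convrep
Title: Word and Topic Repetition Features from Longitudinal Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts word- and topic-repetition features from longitudinal
    conversation transcripts, both within single conversations and across
    pairs of conversations separated by configurable day or call-count
    intervals, together with 29 standard linguistic features (part-of-speech
    profiles, vocabulary richness, syntactic complexity, perseveration), and
    ranks the power of every feature to discriminate speakers with Alzheimer
    disease from controls via Cohen's d effect sizes and AUC-ROC. Includes a
    biterm topic model fitted by collapsed Gibbs sampling, interval-window
    pairing of calls with a grid search over the interval parameter, and a
    seeded generator of synthetic longitudinal conversation corpora with
    controllable group differences in cross-day topic reuse, within-call
    repetition, vocabulary richness and part-of-speech composition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
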