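Package: enhancerCNN
Title: Enhancer Identification and Strength Classification with
    Ensembles of Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies enhancer regions among fixed-length (200 bp) DNA
    sequences and classifies identified enhancers as strong or weak.
    Each sequence is encoded as an L x 8 matrix combining one-hot
    nucleotide channels with positional 1-, 2- and 3-mer whole-sequence
    occurrence frequencies, and scored by an averaged ensemble of five
    one-dimensional convolutional neural networks trained by rotating
    stratified 5-fold cross-validation. Includes the full evaluation
    protocol (ACC, SN, SP, MCC, AUC over repeated independent-test
    trials), a two-sample-logo-style positional nucleotide enrichment
    test, and a synthetic benchmark generator with class-dependent GC
    content for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
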