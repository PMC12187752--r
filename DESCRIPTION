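Package: kcrnet
Title: Lysine Crotonylation Site Prediction with Dense Convolutional
    Networks and Residual Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine crotonylation (Kcr) sites from 29-residue
    peptide windows centered on a lysine. Windows are tokenized into
    k-mers, encoded by a trainable skip-gram word embedding (or a one-hot
    baseline), and classified by a densely connected 1-D convolutional
    network whose final feature maps are re-weighted by a residual
    channel attention mechanism. Includes FASTA window extraction, a
    seeded synthetic motif-data generator with exact Bayes-accuracy
    computation, stratified cross-validation, an architecture grid
    search, confusion-matrix and ROC/AUC evaluation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
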