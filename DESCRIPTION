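Package: peptidecrf
Title: Length-Constrained Conditional Random Fields for Cleaved Peptide
    Prediction in Precursor Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence labeling of peptide and propeptide spans in precursor
    protein sequences with a linear-chain conditional random field whose state
    space enforces a minimum and maximum span length (5-50 residues by default)
    and forbids direct transitions between span classes. Provides exact
    log-partition, Viterbi decoding and forward-backward marginals over the
    constrained state space, class-tied emission scoring with pluggable
    front-ends (one-hot residue encoding, a CNN-LSTM-CNN network, or
    precomputed per-residue embeddings), end-to-end gradient training with
    early stopping on span-level F1, ensemble averaging of replicate models,
    span-level precision/recall/F1 with tolerance windows and overlap-cluster
    collapsing, annotation filtering and cluster-stratified fold assignment,
    and a synthetic precursor-proteome generator with planted cleavage-flank
    motifs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
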