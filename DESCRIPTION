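Package: kdeep
Title: Two-Level k-mer (FCGR) Encoding and CNN-BiLSTM Prediction of
    DNA/RNA Protein Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the KDeep approach to transcription-factor and
    RNA-binding-protein binding-site prediction. Sequences are encoded with
    2Lk, a two-level k-mer scheme in which an outer sliding window of size
    k1 traverses the strand and every windowed word is profiled by its
    frequency chaos game representation (FCGR) at resolution k2, giving an
    (L - k1 + 1) x 4^k2 matrix per strand. Encoded strands feed a
    convolutional network followed by a bidirectional LSTM (KDeep), with an
    optional additive attention block (KDeep+). First-layer convolution
    filters are converted back to sequence motifs (PFM -> PWM) and exported
    in MEME minimal motif format for comparison against motif databases;
    attention scores are exported as per-position heatmaps. A synthetic
    motif-implantation generator and oracle-verified auROC/auPRC metrics
    make the full pipeline testable without external benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Epigenetics, MotifDiscovery, Transcription,
    Classification, NeuralNetwork
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
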