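Package: bindsignal
Title: Base-Resolution Modeling of TF-DNA Binding Signals with a Fully
    Convolutional Encoder-Decoder
Version: 0.1.0
Authors@R: person("bindsignal", "developers", role = c("aut", "cre"),
    email = "maintainers@bindsignal.dev")
Description: Trains a symmetric fully convolutional encoder-decoder network
    (convolution blocks, a bidirectional GRU bottleneck with global average
    pooling, and bilinear-upsampling decoder stages with skip connections)
    to regress per-base transcription-factor binding signal from DNA
    sequence. From the predicted base-resolution signal the package derives
    binding/non-binding classification (sigmoid of the signal maximum),
    binding-region localization (signal argmax), whole-chromosome scanning,
    in-silico SNP effect scores, a chromatin-openness statistic, and
    position frequency matrix (motif) extraction from first-layer
    convolutional filters. Includes readers for FASTA, BED and bedGraph, a
    MEME-format motif writer, evaluation metrics (MSE, Pearson r, AUROC,
    AUPRC), and a synthetic motif-planting data generator so the full
    pipeline is trainable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
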