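Package: braingcn
Title: Brain-Network Graph Convolutional Classification of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for two-class (depressed vs. control) classification of
    multichannel resting-state EEG. Recordings are notch- and bandpass-filtered,
    baseline-corrected and cut into overlapping windows; each window is
    decomposed into the canonical delta/theta/alpha/beta bands and summarised
    by per-band differential entropy, giving a channels x time x bands feature
    tensor. A shared-weight bidirectional LSTM encodes each channel's band
    sequence into graph node features; a Pearson-correlation brain network over
    the channels supplies the adjacency, and a graph convolutional network with
    bounded-ReLU activations and 50 percent graph coarsening performs the
    classification. Includes a synthetic EEG generator with class-dependent
    band power and community-structured inter-channel correlation, subject-wise
    k-fold cross-validation with leakage-free per-fold graph and normalisation
    fitting, and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
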