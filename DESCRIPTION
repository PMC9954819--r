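Package: deepeeg
Title: Convolutional-Autoencoder and Bi-LSTM Models for EEG Seizure
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of epileptic seizures in multichannel scalp EEG with
    a deep convolutional autoencoder (DCAE) whose latent representation
    feeds multilayer-perceptron, LSTM or bidirectional-LSTM classification
    heads, trained jointly on a reconstruction plus cross-entropy objective.
    Includes EDF reading and writing, parsing of CHB-MIT style seizure
    annotation summaries, non-overlapping segmentation with z-score and
    min-max normalisation, class balancing, a seeded synthetic EEG
    generator (band-limited background, spike-wave ictal discharges, EMG,
    ocular and white-noise artifacts), stratified k-fold cross-validation
    and confusion-matrix metrics. Network forward and backward passes are
    implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
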