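Package: eegkpca
Title: Entropy Features and Kernel PCA for EEG Mental-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for recognising mental states (such as driver fatigue)
    from multichannel physiological recordings. Extracts per-epoch,
    per-channel complexity features (sample entropy, fuzzy entropy, and a
    pluggable combination-entropy slot), reduces the epoch-by-channel
    feature matrix with principal component analysis or kernel PCA over a
    registry of Mercer kernels (linear, polynomial, radial basis, sigmoid),
    selects components by cumulative variance contribution, and classifies
    the reduced scores with a built-in support-vector machine under a
    stratified cross-validation protocol. Includes a two-state synthetic
    EEG-like signal generator so the full pipeline is testable without
    access to clinical recordings, plus delimited-text and EDF readers and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
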