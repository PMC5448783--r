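Package: eegdecode
Title: Decoding Visual Object Categories from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Multivariate pattern analysis of multichannel EEG epochs for
    decoding visual stimulus categories. Features are extracted with a
    single-layer 1-D convolutional feature bank of random kernels followed
    by non-overlapping pooling, ranked by Welch two-sample t-tests, and
    classified with a likelihood-ratio-based score-fusion rule built on
    per-class, per-feature Gaussian kernel density estimates. Includes a
    synthetic evoked-response generator (1/f plus white noise), a minimal
    EDF reader/writer and zero-phase Butterworth band-pass filtering for
    epoching continuous recordings, discrete-wavelet and support-vector
    baselines, Monte-Carlo cross-validation, and permutation/binomial
    chance-level estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
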