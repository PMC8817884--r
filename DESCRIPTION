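Package: eegdepth
Title: EEG-Based Depth-of-Anesthesia Indices and a Convolutional Depth Regressor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring propofol depth of anesthesia from single-channel
    EEG. Computes the classical per-epoch sedation indices (sample entropy,
    permutation entropy, wavelet entropy, alpha/beta band-power ratios, median
    and spectral-edge frequencies, and documented surrogates for approximate
    entropy, synch-fast-slow and spectral entropy), compares candidate indices
    against a reference depth series by correlation banding, assembles 24x24
    feature images from consecutive epochs, and trains a small convolutional
    regressor with a scaled dot-product self-attention block and residual
    connections that outputs a BIS-like 0-100 depth index. Includes a seeded
    synthetic anesthesia-cohort simulator so the full pipeline runs end to end
    without clinical recordings, plus phase-stratified evaluation reports
    (R squared, RMSE, MAPE, accuracy within tolerance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
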