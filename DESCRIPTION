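Package: eegdenoise
Title: Adversarial and Wavelet Artifact Removal for EEG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for removing physiological artifacts (eye blinks, eye
    movements, chewing, teeth clenching) from multichannel EEG. Implements a
    wavelet detail-coefficient thresholding cleaner with Savitzky-Golay
    detrending, an adversarially trained LSTM sequence-to-sequence denoiser
    (generator/discriminator pair with a weighted MSE + binary cross-entropy
    objective), a seeded synthetic-session simulator with ground-truth clean
    traces, the standard preprocessing chain (band-pass filtering, min-max
    normalization, epoch clipping, fixed-window segmentation, subject-held-out
    splitting), a five-metric evaluation suite (NMSE, RMSE, correlation, band
    signal-to-noise ratio, signal-to-artifact ratio), and EDF/CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
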