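Package: fessemg
Title: Motion and Muscle-Fatigue Recognition from FES-Contaminated Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for recognizing lower-limb motion intent
    and muscle-fatigue state from surface electromyography (sEMG) recorded
    during functional electrical stimulation (FES). Provides a seeded
    synthetic-data generator for FES-contaminated multi-channel sEMG,
    stimulation-artifact removal by empirical mode decomposition combined
    with notch filtering, conversion of 500-ms windows into time-frequency
    images (short-time Fourier spectrogram, bump-wavelet scalogram, and
    Hilbert-Huang spectrum), a parallel CNN+LSTM dual-task network that
    jointly classifies six motions and three fatigue states, hand-crafted
    time-domain and spectral feature baselines with linear discriminant
    analysis, and evaluation utilities linking row-normalized confusion
    matrices to precision/recall/F1 tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
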