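Package: rppgfilter
Title: LSTM Deep Filtering and Quality Assessment of Remote
    Photoplethysmography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for denoising one-dimensional remote photoplethysmography
    (rPPG) traces with a recurrent (LSTM) sequence-to-sequence deep filter, in
    both many-to-one (next-sample forecasting) and many-to-many (windowed
    denoising with overlap-add reconstruction) variants, implemented natively
    with compiled single-precision numerics.  Ships the classical baseline
    filters the deep filter is compared against (zero-phase Butterworth
    bandpass, wavelet sub-band denoising, Savitzky-Golay), windowed FFT heart
    rate estimation, four signal-quality metrics (heart-rate MAE, Pearson r,
    harmonic-band SNR, template match correlation), a synthetic pulse-signal
    corpus generator with closed-loop SNR targeting, and subject-independent
    evaluation protocols (cross-validated intra-corpus, cross-corpus,
    amount-of-training-data, and SNR-stratified).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
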