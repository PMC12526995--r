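Package: mdcpr
Title: Micro-Doppler Radar Analysis of CPR Chest-Compression Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for estimating chest-compression
    depth during cardiopulmonary resuscitation (CPR) from the micro-Doppler
    signature of a frequency-modulated continuous-wave (FMCW) radar. Provides
    a compression-kinematics and radar-signal simulator (phase-level and
    chirp-level), joint time-frequency representations (STFT spectrogram,
    Wigner-Ville distribution and its smoothed pseudo variant), a
    Doppler-integration depth estimator with envelope detection and cycle
    segmentation, a closed-form polynomial regression on per-cycle peak
    Doppler frequency, a small convolutional neural network regressor on
    spectrogram images with leave-one-subject-out evaluation, and the
    summary statistics (RMSE, Student-t confidence intervals, paired t-test)
    used to report results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
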