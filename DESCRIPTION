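Package: mibci
Title: Motor-Imagery EEG Classification with Hybrid Time and
    Wavelet-Packet Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete two-class motor-imagery brain-computer-interface
    (BCI) pipeline for multichannel EEG: zero-phase Butterworth band-pass
    and 60 Hz notch filtering, per-channel z-score normalization, cue-locked
    epoch segmentation, six time-domain features (RMS, quadratic Renyi
    entropy, Hjorth mobility and complexity, waveform length, mean absolute
    value), a four-level wavelet packet decomposition feature bank (six
    statistics per frequency-ordered terminal sub-band), hybrid
    correlation-based filter plus classifier-wrapper forward feature
    selection, and stratified 10-fold cross-validated evaluation of linear
    SVM, LDA, and k-NN classifiers with a full metric suite (accuracy,
    sensitivity, specificity, precision, F1, AUC).  Includes EDF and
    delimited matrix-bundle readers and writers, a named sensorimotor
    channel-set registry, a synthetic mu/beta motor-imagery EEG generator
    with known ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    e1071,
    MASS,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
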