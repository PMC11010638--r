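Package: csbn
Title: Music-Evoked EEG Emotion Recognition with Differential-Entropy
    Features and a CNN-Attention-BiLSTM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising music-evoked emotional states from
    multichannel electroencephalography (EEG). Recordings are band-pass
    filtered, downsampled, baseline-corrected and cut into 2-second Hann
    windows; each window is decomposed into the theta, alpha, beta and
    gamma bands with order-3 Butterworth filters and summarised by
    per-channel, per-band differential entropy. Binary valence and
    arousal labels (rating threshold 5 on the 1-9 self-assessment scale)
    are classified by the CSBN network: a one-dimensional convolutional
    stack with multiplicative residual connections, scaled dot-product
    self-attention, a three-layer bidirectional LSTM and a softmax head,
    trained with Adam on the cross-entropy loss. Includes a seeded
    synthetic-EEG generator with class-dependent band-power signatures,
    stratified 10-fold cross-validation, and ablation, single-band and
    band-combination experiment suites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
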