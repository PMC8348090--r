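Package: jawdio
Title: Acoustic Classification of Dairy Cow Ingestive Behaviors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying dairy cow ingestive behaviors (bites,
    chews, and chew-bites) from forehead-microphone recordings. Provides
    a synthetic ingestive-sound generator parameterized by published
    per-behavior amplitude and duration statistics, WAV segment and
    manifest handling, data cleaning (zero-phase bandstop removal of
    device beeps, block-mean removal of uninformative low-power audio),
    log-Mel spectrogram featurization, three small neural network
    classifiers (time-distributed Conv1D, Conv2D, and bidirectional
    LSTM) with a deterministic training loop, dataset balancing and
    stratified splitting, forage-stratified evaluation, and
    precision/recall/F1 reporting with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
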