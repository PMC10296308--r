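Package: eegaffect
Title: Personality-Conditioned Emotion Recognition from EEG Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for four-quadrant (arousal-valence)
    emotion recognition from multichannel EEG, conditioned on Big Five
    personality traits. Provides EDF reading and writing with stimulus
    annotations, a preprocessing chain (decimation, Butterworth band-pass,
    power-line notch, ICA-based blink removal, overlapping 2-second windows
    with baseline adjustment), short-time Fourier spectrogram images, a
    convolutional emotion branch, a stacked LSTM personality branch trained
    with leave-one-subject-out cross-validation, feature fusion with a bank
    of final-stage classifiers, one-vs-rest confusion metrics with ROC/AUC,
    and a seeded synthetic-EEG generator that emulates the three-group
    (Unstable Introvert, Unstable Extrovert, Normal) image/video stimulation
    protocol so that every stage is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    nnet,
    class,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
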