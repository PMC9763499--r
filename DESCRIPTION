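Package: spotcall
Title: Animal-Independent Bioacoustic Signal Detection and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectrogram-based deep-learning toolkit for bioacoustic sound
    event detection and classification. Provides a species-parameterized
    preprocessing pipeline from raw PCM audio to normalized power-spectrogram
    network inputs (resampling, STFT, spectrogram-domain augmentation, linear
    frequency compression, SNR-controlled noise mixing, decibel conversion
    and normalization), a modified 18-layer residual network classifier
    without the initial max-pooling stage, recording-exclusive dataset
    splitting, CPU training with plateau learning-rate decay and early
    stopping, sliding-window detection with frame smoothing and annotation
    extraction, time-wise and frame-wise evaluation against selection-table
    ground truth, two-stage detect-then-classify inference with a noise
    override rule, and a seeded synthetic corpus generator so the whole
    pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
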