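Package: facesurv
Title: Multimodal Seven-Day Survival Prediction from Facial Features and
    Clinical Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multimodal framework for predicting seven-day survival of
    clinical patients. Implements a lightweight face-region convolutional
    detector (a residual stem, a staged convolutional body and a
    path-aggregated feature pyramid with bicubic upsampling) that localizes
    eyes and lips in patient images, a recurrent tabular classifier that
    combines an LSTM with adaptive attention, a sigmoid gate and a
    batch-normalized residual block, a fusion stage that turns detections
    into facial feature vectors and concatenates them with 36 physiological
    indicators, COCO-style detection metrics and threshold-based
    classification metrics, group-comparison and dichotomous logistic
    regression analyses of survival factors, and a synthetic-data module
    that emulates both modalities with known generative structure so the
    whole pipeline is testable without access to a private cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
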