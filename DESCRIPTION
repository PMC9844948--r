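Package: vsr2stage
Title: Two-Stage Visual Speech Recognition with Intermediate Audio Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-stage lip-reading (visual speech recognition) pipeline for
    assistive communication with speech-impaired patients. Silent mouth-region
    video is first mapped to an intermediate acoustic representation (log-Mel
    or MFCC features, one feature row per 40 ms video frame) by a
    spatio-temporal convolutional + recurrent Audio Feature Estimator; a
    second convolutional-recurrent network transcribes the features to
    per-frame character distributions trained with the Connectionist Temporal
    Classification (CTC) loss, optionally fine-tuned on the first stage's
    predictions; decoded sentences pass an edit-distance unigram spell
    corrector. Includes frame-synchronized MFCC extraction, per-video
    consistent visual augmentation, character/word error rate evaluation and
    a synthetic audiovisual corpus generator for end-to-end testing at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
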