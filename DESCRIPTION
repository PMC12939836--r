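Package: bandelet
Title: Geometry-Adaptive Bandelet Transform and Classification Pipeline for
    Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the second-generation bandelet transform for 2D
    greyscale images: quadtree best-basis selection under a Lagrangian
    rate-distortion cost, per-block geometric flow estimation, and exactly
    invertible bandeletisation of wavelet detail subbands. Around the
    transform it provides the full workflow used for ultrasound
    thyroid-nodule classification studies: a seeded B-mode speckle phantom
    generator, SMOTE oversampling and geometric data augmentation,
    four-channel bandelet feature tensors with z-score normalisation, a
    small trainable convolutional classifier with a freeze-then-unfreeze
    transfer-learning schedule, and confusion-matrix metrics with
    repeated k-fold descriptive statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
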