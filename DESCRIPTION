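Package: bcsnet
Title: Lightweight Tail-Image Body Condition Scoring for Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates lightweight convolutional classifiers that
    read dairy-cattle body condition scores (BCS, five ordinal classes from
    3.25 to 4.25) from tail-region images. Provides a zoo of six reference
    mobile backbones with exact trainable-parameter accounting,
    squeeze-and-excitation channel attention, spatial attention, a
    depthwise-separable convolutional classification head, label-smoothing
    and knowledge-distillation losses, Adam training with early stopping and
    grid search, confusion-matrix and BCS tolerance-accuracy evaluation,
    Grad-CAM explanation, and a class-conditional synthetic tail-image
    generator so the full pipeline is testable without the source dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
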