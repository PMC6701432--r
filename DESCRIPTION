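Package: fbcnn
Title: Feedback-Gated Convolutional Networks for Patch-Based Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small, fully traced convolutional network engine together with a
    gate-switch reinterpretation of its ReLU and max-pooling layers. Binary
    feedback gates attached to every rectifier neuron are optimized by two
    greedy schemes, top-down feedback recovery and bottom-up feedback
    selection, that screen the neurons relevant to a chosen output (target)
    neuron and yield input-space saliency and energy maps. On top of the
    engine sits a patch-wise pixel classification pipeline for lesion
    segmentation in grayscale medical-style images, with intensity-band
    thresholding and morphological opening/closing refinement, Dice/IoU
    evaluation, and a seeded synthetic lesion-scene generator providing
    pixel-accurate ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
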