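Package: confaug
Title: Detector-Feedback Copy-Paste Augmentation for Dense Cell Instance Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training-time data augmentation and evaluation in dense
    instance segmentation of round spermatid-scale cells in microscopy images.
    Maintains bounded first-in-first-out "zoos" of confusing regions harvested
    from per-iteration detector output (low-confidence hits on true objects and
    high-confidence hits on background), pastes sampled zoo regions back into
    training images ("confusion duplicate"), and zeroes k-by-k blocks confined
    to informative regions ("regional drop"). Includes annotation-aware
    preprocessing (alpha removal, square padding, bilinear resizing, channel
    duplication, colour normalisation, flips, Gaussian noise and blur), COCO
    JSON reading and writing with run-length and polygon mask decoding, a
    per-image precision-weighted mean average precision metric with a
    union-overlap match rule, and a synthetic microscopy scene generator with a
    configurable mock predictor for end-to-end desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
biocViews: CellBiology, Segmentation, Preprocessing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
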