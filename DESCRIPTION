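Package: athermoseg
Title: Adaptive Entropy-Based Multilevel Thresholding for Thermal Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of single-channel thermal infrared images by
    multilevel histogram thresholding. Implements an adaptive entropy objective built
    on a tangent-of-logarithm kernel over segment-normalised intensity probabilities,
    together with Shannon, Tsallis, Renyi, Kapur and Masi entropy baselines, exact
    exhaustive and dynamic-programming threshold search, adaptive gamma and
    logit-based contrast enhancement, an iterative segment-posterize-binarize
    pipeline producing a binary region-of-interest mask, block-based no-reference
    contrast metrics (EME, EMEE, AME, AMEE and a block entropy metric), a
    segmentation evaluation suite (accuracy, Dice, Jaccard, precision, recall,
    boundary F1 and a combined score), and deterministic synthetic thermal scene
    generators for testing without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
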