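Package: flowseg
Title: Self-Supervised Cell Segmentation from Single Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, per-image cell segmentation for fluorescence and
    label-free microscopy. Each image supplies its own training data: dense
    Farneback optical flow between the image and a Gaussian-blurred copy marks
    high-confidence cell and background pixels (flow thresholds are self-tuned
    by maximising the local-entropy difference between the two candidate
    classes), an image-specific Gaussian naive Bayes classifier is trained on
    entropy, gradient and intensity features at those pixels, and every pixel
    is then classified to produce a binary mask. Includes mask cleanup,
    optional watershed declumping of touching cells, pixel-level F1
    evaluation, a seeded synthetic-microscopy fixture generator, and batch
    processing with per-image models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    jpeg,
    optparse
Config/testthat/edition: 3
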