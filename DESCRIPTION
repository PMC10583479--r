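Package: slidedx
Title: Two-Stage Whole-Slide Tumor Diagnosis by Patch Majority Voting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale implementation of a two-stage whole-slide-image
    diagnosis pipeline for seven common canine skin tumor types: tissue
    segmentation into six classes, full-tumor patch tiling at the
    classification resolution, patch-wise tumor-type classification, and
    majority-vote aggregation into a ranked slide diagnosis. Includes a
    synthetic cohort generator (label rasters, stochastic segmenter and
    classifier oracles, simulated pathologist panels), the training-side
    patch sampling rules (uniform and adaptive class reweighting, 90
    percent purity rule), pathologist consensus statistics
    (confidence-ranked votes, draw tie-break, decimal consensus), and an
    evaluation suite (slide- and patch-level confusion matrices,
    precision/recall/F1 under both the conventional and the reported
    table conventions, PCA feature projections).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
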