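Package: gleasonCascade
Title: Multi-Stage Gleason Grading of Prostate Biopsy Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for Gleason-pattern classification of
    digitized prostate biopsy slides: histogram equalization and unsharp-mask
    edge enhancement, pyramidal overlapping tiling (three patch sizes with
    thirteen complete tilings each, 39 in total), per-level cascades of four
    binary classifiers resolving the five Gleason patterns, pixel-wise
    majority-vote fusion, and slide-level Gleason score / ISUP grade-group
    assignment. Includes a seeded synthetic-slide generator with per-pixel
    ground truth, a from-scratch tiny convolutional network backend, an
    oracle backend for plumbing tests, evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
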