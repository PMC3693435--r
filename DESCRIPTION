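Package: mammodensity
Title: Semi-Automated Percent Mammographic Density from Digital Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures percent mammographic density (PD) in full-field digital
    mammograms with a semi-automated two-threshold pipeline: contrast and
    brightness normalization, a breast-thickness brightness correction driven
    by a chest-to-edge distance map, breast segmentation by a proposed Otsu
    threshold with largest-connected-component selection and manual region
    invalidation, and dense/fat classification by a second threshold, giving
    PD = DT/(DT+FT)*100. Includes the rater-agreement statistics used to
    validate such tools (Lin's concordance correlation coefficient,
    Bland-Altman difference summaries, quadratic-weighted kappa against the
    Boyd semiquantitative scale), a synthetic phantom generator with exact
    ground truth for end-to-end testing without clinical images, and a batch
    driver with a file-based session format replacing interactive adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
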