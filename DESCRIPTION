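Package: thighmorph
Title: Thigh Muscle Morphometry from MRI Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies thigh muscle morphology from per-slice MRI
    segmentations: maximal anatomical cross-sectional area (ACSAmax) of the
    ten knee extensor and flexor muscles, summed muscle-group sizes and the
    knee flexor to extensor (KF:KE) size ratio, proportional muscle sizes,
    and femur-length-normalized mass-distribution curves interpolated on a
    fixed percent-femur-length grid. Provides the accompanying statistical
    battery (independent t-tests, mixed two-way ANOVAs, Holm-Bonferroni
    post-hoc correction, Cohen's d, contiguous significant-region extraction
    along the femur) and a synthetic cohort generator with sex-specific
    muscle size distributions for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
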