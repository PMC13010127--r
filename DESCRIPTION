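Package: preful
Title: Phase-Resolved Functional Lung MRI Analysis with a Digital Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open analysis pipeline for phase-resolved functional lung MRI
    (PREFUL) from free-breathing 2D+t proton MRI time series: respiratory
    signal extraction and phase sorting, mid-expiration nonrigid registration,
    lung segmentation, voxel-wise regional ventilation, normalized perfusion
    and flow-volume-loop correlation maps, defect classification (VDP, QDP,
    V/Q match), severity stratification, and a nonparametric cohort statistics
    layer. Includes a seeded dynamic lung phantom generator with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    signal,
    pracma,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
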