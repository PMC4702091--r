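Package: cordmorph
Title: Semi-Automated Spinal Cord Cross-Sectional Morphometry at C2
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automated measurement of spinal cord cross-sectional area
    (SCA), anterior-posterior width (APW) and left-right width (LRW) from
    T1-weighted MRI at the C2 vertebral level: seeded best-first region
    growing with a relative-intensity stopping criterion, direct
    least-squares ellipse fitting of the region boundary, superior slice
    propagation over a 1.5 cm window, and quality control. Includes a
    NIfTI phantom generator with analytic ground truth, a synthetic
    spinal-cord-injury cohort simulator calibrated to published group
    summary statistics, and the nonparametric/regression/correlation
    battery used to relate cord morphometry to injury group and
    below-level neuropathic pain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0), methods
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
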