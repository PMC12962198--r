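Package: cestquant
Title: CEST MRI Z-Spectrum Processing, Lorentzian Fitting and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processing pipeline for chemical exchange saturation transfer
    (CEST) MRI of the brain: rigid motion correction of multi-offset volume
    series, Z-spectrum normalization and cubic-spline interpolation,
    voxel-wise B0 correction by the minimum-of-Z-spectrum approach, MTR
    asymmetry mapping at configurable offsets (1, 2 and 3.5 ppm by default),
    ROI-averaged six-pool Lorentzian fitting with bounded nonlinear least
    squares, FreeSurfer-style ROI management (bilateral merging, composite
    regions, ventricular exclusion, common-ROI intersection), and exact
    small-sample Mann-Whitney U group comparisons. Includes a seeded
    synthetic phantom generator with ground truth so that every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
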