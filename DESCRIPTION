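Package: contourQA
Title: Data Integrity Checks for Radiotherapy Organ Contours
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometric data-integrity checking for binary organ-at-risk
    structure masks used in radiotherapy planning. Masks are stored as
    run-length encoded voxel sets on anisotropic grids; the package computes
    volume, per-axis extent, slice-based extent profiles and extent ratios,
    applies two contiguity checks (axis-projection extent completeness and
    flood-fill region growing with a fixed-radius neighbour rule), and runs
    cohort-level percentile-threshold outlier models for bladder, femoral
    head and tubular (rectum, spinal cord) contours. A deterministic
    synthetic phantom generator with controllable defect injection provides
    ground-truth-labelled cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
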