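Package: cmragree
Title: Agreement Analysis of CMR-Derived Left Ventricular Strain and Volume Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the repeatability and reproducibility of left
    ventricular metrics derived from short-axis cardiac magnetic resonance
    segmentations. Provides a synthetic deformable left-ventricle phantom with
    analytic ground truth (per-slice radii, perimeters, areas, volumes and
    circumferential strains), contour geometry for the two measurement chains
    compared in inter-software studies (periodic cubic spline contours and
    convex hulls of binary masks), composite midpoint volume integration,
    endocardial circumferential strain with regional grouping, ejection
    fraction, and the agreement-statistics layer used in multi-reader
    multi-software studies: group summaries, paired comparisons with
    Bonferroni correction, and Bland-Altman analysis of contour lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
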