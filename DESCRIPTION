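Package: organoidscreen
Title: Multi-Parametric Morphometric Profiling of 3D Organoid Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for high-content phenotypic screening of
    tumour-derived organoids imaged as two-channel fluorescence z-stacks
    (nuclei and F-actin). Provides a ground-truth-labelled synthetic image
    generator emulating a multi-well screen with dose-dependent morphology
    changes, maximum-intensity-projection segmentation of organoid, lumen and
    nucleus masks with out-of-focus filtering, extraction of a ~600-column
    per-well morphometric feature profile, PCA-based selection of the most
    discriminating features between vehicle-control and high-dose wells,
    Euclidean-distance phenotypic scoring against the control centroid, and
    four-parameter logistic dose-response fitting with EC50 estimation and a
    fit / no-fit decision. Auxiliary calculations for viability normalization,
    delta-delta-Ct fold changes and culture derivation rates are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Visualization, Segmentation, FeatureExtraction
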