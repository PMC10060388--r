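Package: facewarp
Title: Landmark-Based Geometric Morphometrics of Facial Ontogeny in Great Apes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-dimensional landmark-based
    geometric morphometrics of facial shape, built around the comparison of
    adult and infant faces across hominid species. Reads and writes tpsDig
    landmark files and slider definitions, performs generalized Procrustes
    superimposition with sliding semilandmarks (bending-energy or
    Procrustes-distance criterion), decomposes shape variation into relative
    warps (shape principal components), and quantifies how reliably each
    shape axis separates age classes using a battery of classifiers (LDA,
    linear and radial-kernel SVMs with grid-search tuning), cross-validated
    accuracy/AUC, and permutation-test inference. Includes intra-annotator
    landmark reliability (ICC), thin-plate-spline deformation grids, and a
    synthetic face-landmark generator with known species structure and
    planted age-effect axes for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
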