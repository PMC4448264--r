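Package: nestquant
Title: Quantitative Morphology of Tumor Nests in H&E Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided image analysis pipeline for hematoxylin-eosin
    (H&E) stained breast-cancer histopathology. Segments tumor nests and
    stroma with a pixel-wise support vector machine, segments cell nuclei
    with a marker-controlled watershed, classifies nuclei into epithelial,
    stromal round and stromal non-round populations, extracts a 730-parameter
    multi-level morphologic feature catalog (pixel, object and semantic
    levels, including box-counting fractal dimension and Delaunay spatial
    statistics), builds composite prognostic features, and runs
    cutpoint-based survival analysis (Kaplan-Meier with log-rank tests,
    Cox proportional hazards, ROC). Ships synthetic H&E image and survival
    cohort generators with ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    survival,
    pROC,
    deldir,
    tibble,
    generics,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    grDevices,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    png,
    tiff
Config/testthat/edition: 3
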