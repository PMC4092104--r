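Package: adipomorph
Title: Automated Adipocyte Morphometry for Elastic-Stained Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies adipose-tissue histology from brightfield images of
    elastic-stained sections. Detects one seed per adipocyte lumen from the
    distance transform of a color-threshold stain classification, computes a
    gradient-vector-flow (GVF) external force field from color gradients, and
    evolves a closed deformable contour (snake) per seed to recover each
    adipocyte boundary and cross-sectional area in square micrometres.
    Also reports collagen and elastin area fractions of the tissue, normalizes
    counted objects (mast cells, macrophages, vessels) to events per square
    millimetre, and provides paired pre/post statistics on per-slide summaries.
    Includes a synthetic stained-slide generator with exact ground truth so the
    whole pipeline is testable without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
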