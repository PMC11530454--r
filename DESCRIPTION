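Package: stainshift
Title: Interpretation Shift in PHH3-Assisted Mitotic Figure Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying the information
    mismatch between hematoxylin-and-eosin (H&E) morphology and
    phospho-histone-H3 (PHH3) immunohistochemistry in mitotic figure
    annotation. Generates co-registered synthetic H&E/PHH3 image pairs with
    known cell-level ground truth, simulates multi-expert two-phase
    annotation studies with hindsight bias, builds distance-clustered
    consensus label sets, computes inter-rater agreement statistics
    (leave-one-out precision/recall/F1, intraclass correlation, Fleiss'
    kappa, paired significance tests), trains single-stain and dual-stain
    mid-fusion anchor-free detectors, evaluates them with tiled inference
    and distance-matched average precision over a train-label by eval-label
    experiment grid, and reproduces a latent-space decision-boundary
    analysis via embeddings, UMAP projection and highest-density regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    igraph,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
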