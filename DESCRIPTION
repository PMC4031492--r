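Package: signalpls
Title: Partial Least Squares Modeling of Phosphoprotein Signaling and Cell
    Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links phospho-ELISA measurements of signaling-protein
    phosphorylation to relative cell survival with partial least squares
    regression (SIMPLS), leave-one-out cross-validation, and
    randomization-based model significance. Includes ELISA standard-curve
    calibration, design-matrix assembly with autoscaling, coefficient
    ranking and incremental-feature models, pairwise phosphosite
    correlation networks with Storey q-values, hierarchical clustering for
    heatmap ordering, signed ligand-response graph export (GraphML/SIF),
    and a synthetic-data generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
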