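Package: fishmap
Title: Whole-Brain Activity Mapping and Functional Network Analysis for
    Adult Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for whole-brain immediate-early-gene
    (c-fos) activity mapping in adult zebrafish: spatial deduplication of
    detected cell candidates in anisotropic voxel space, a compact 3-D
    convolutional classifier separating punctate from diffuse staining,
    aggregation of classified cells into per-animal regional count tables
    against an atlas label volume, time-course statistics (two-way ANOVA
    with eta-squared, Dunnett many-to-one comparisons, FDR-corrected
    region-wise tests with Cohen's d), and inference of a functional brain
    network from cross-animal regional count correlations with
    efficiency-cost-optimized density selection, Louvain communities,
    node-role classification, centralities, and small-worldness against
    Erdos-Renyi nulls. A synthetic-data module generates count tables with
    planted time-course, community, and hub structure, point clouds with
    planted duplicates, and labeled 3-D volumes, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
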