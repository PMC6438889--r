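Package: bascgraph
Title: Bootstrap-Stable Cluster Connectomes and Cost-Thresholded Graph
    Analysis for Resting-State Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step analysis pipeline for multi-subject region-by-time
    resting-state series. Step one derives data-driven functional parcels by
    bootstrap analysis of stable clusters (BASC): hierarchical Ward clustering
    replicated under a circular block bootstrap at the individual level and a
    subject bootstrap at the group level, with consensus partitions extracted
    over a multiresolution grid; cluster-by-cluster Fisher-z connectomes are
    then compared between groups with connection-wise linear models,
    Benjamini-Hochberg false-discovery control per resolution, and a
    label-permutation omnibus test pooling discoveries across resolutions.
    Step two thresholds correlation matrices into binary graphs over a cost
    range, computes efficiency and small-world omega curves, averages degree
    and betweenness centrality over the cost range, selects hub nodes by a
    mean-plus-one-standard-deviation rule, and runs group contrasts, two-way
    subgroup ANOVAs, and degree-cognition correlations. A synthetic-cohort
    generator with planted modular structure, hubs, group effects, and
    covariate coupling provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
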