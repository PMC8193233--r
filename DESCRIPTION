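Package: clppnet
Title: Community Physiological Profiles and Co-Occurrence Networks for
    Pore-Water Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired 16S OTU tables and Biolog
    EcoMicroplate readings from peatland pore-water samples. Computes
    community-level physiological profiling metrics (average well-colour
    development, McIntosh and Shannon indices, AWCD-normalised response
    intensities and their PCA), alpha and beta diversity with rarefaction,
    PERMANOVA and PCoA, redundancy analysis with Monte-Carlo permutation
    tests, Spearman/FDR co-occurrence networks over abundant OTUs and
    environmental variables with Erdos-Renyi null ensembles and keystone
    identification, and permutation-based indicator species (IndVal)
    selection. Ships a synthetic-data generator with planted correlation
    modules and indicator OTUs for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
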