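Package: hilldrift
Title: Hill-Number Diversity and Null-Model Analysis of Disturbed Reactor
    Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-assembly analysis for amplicon sequence variant (ASV)
    count tables from replicated bioreactor time series. Computes Hill-number
    taxonomic diversity and distance-based (phylogenetic) diversity expressed
    as total effective distance, pairwise beta-diversities normalised to
    [0,1] dissimilarity indices, Hill-based Raup-Crick standardized effect
    sizes, beta mean nearest-taxon distance (betaMNTD) and its standardized
    effect size (betaNTI) under tip-label randomization, time-decay rates of
    community similarity, and permutation PERMANOVA. Includes a
    granule-structured neutral community simulator (Wright-Fisher drift,
    periodic removal of half the biomass, optional tree-correlated selection)
    so the full pipeline can be exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
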