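Package: poolforge
Title: Simulation and Sequence Analysis of Spontaneous Ligation and
    Recombination in Random Oligonucleotide Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying non-enzymatic ligation and recombination in
    random-sequence genetic oligomer pools. Provides a stochastic
    hydrolysis-ligation pool simulator with Shannon-diversity accounting
    (delta-D landscapes over hydrolysis/ligation rate grids), generators for
    synthetic bait-prey ligation products with tunable junction dinucleotide
    bias and truncation ladders, read preprocessing (quality filtering,
    collapsing, adapter trimming, length splitting), positional
    nucleotide-frequency RGB signatures, ligation-junction dinucleotide
    fingerprints, matched-frequency synthetic pools, secondary-structure
    profile comparison with an exact base-pair-maximization folder,
    junction-proximal structure motif scanning with consensus extraction,
    pool combinatorics, and pseudo-first-order ligation kinetics fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
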