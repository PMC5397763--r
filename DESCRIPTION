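Package: interlock
Title: Co-Evolution, Residue-Network and Interface Analysis of Autoinhibited Two-Domain Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise how one protein domain locks another in an
    autoinhibited complex, from sequence and from structural ensembles.
    Implements pseudocount-corrected mutual information with average-product
    correction on a concatenated two-domain alignment, protein structure
    networks with largest-cluster interaction-strength calibration and
    Floyd-Warshall communication paths over ensembles, and distance-threshold
    interface characterisation (hydrogen-bond occupancy, pseudoenergies,
    hotspot residues) together with standard conformational metrics (RMSD,
    radius of gyration, RMSF). A synthetic-data module generates alignments
    with planted covariation and toy two-chain coordinate ensembles with known
    interfaces and communication paths, so the whole pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
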