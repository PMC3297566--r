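Package: pdzmodes
Title: Binding-Mode Networks, Flexibility Profiles and Family Sequence
    Statistics for PDZ Domain-Peptide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics-like
    trajectories of PDZ domain-peptide complexes and for PDZ family
    sequence analysis. Detects hydrogen bonds and salt bridges with
    geometric cutoffs, encodes each frame as a microstate (binary contact
    pattern plus a leader-clustering conformation id), builds the
    conformation-space network of microstate transitions, lumps it into
    metastable binding modes by gradient clustering, and computes
    time-windowed per-residue backbone RMSF profiles. A companion module
    computes paralog-weighted residue frequencies, loop residue-class
    enrichment (Fisher exact test), helical-propensity profiles of
    C-terminal extensions and group-level permutation p-values over a PDZ
    multiple sequence alignment. Synthetic generators (Markov-chain
    trajectories with Gaussian jitter, planted-enrichment alignments,
    propensity tables) make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
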