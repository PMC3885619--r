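Package: coevokit
Title: Inter-Protein Co-Evolution Analysis for Interacting Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies inter-protein co-evolution between two
    interacting protein families sharing a species tree. Implements
    evolutionary distance and rate estimation (Poisson-corrected p-distance,
    Kimura two-parameter distance, modified Nei-Gojobori dN/dS with
    Kimura-2P correction), MirrorTree-style distance-matrix correlation with
    neutral-marker speciation correction and a Mantel permutation test,
    CAPS-style correlated-mutation detection with connectivity grouping and
    region overlap reporting, clade-specific residue detection, ancestral
    state tracing of a binary interaction trait (Fitch parsimony and a
    two-state Mk model), and a phylogenetic simulator of co-evolving
    families with planted compensatory site pairs for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
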