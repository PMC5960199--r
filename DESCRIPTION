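Package: quartetdiag
Title: Signal Diagnostics for Phylogenomic Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing phylogenetic signal and model violations in
    concatenated multi-gene (supermatrix) datasets. Builds protein-domain-based
    data blocks from masked gene alignments, filters and concatenates them into
    amino acid and codon-partitioned nucleotide supermatrices, screens taxon
    pairs for violations of stationarity, reversibility and homogeneity with
    Bowker's matched-pairs test of symmetry, performs four-cluster likelihood
    mapping (FcLM) with exact quartet likelihoods under GTR+G and LG+G, and
    constructs permutation null matrices (three schemes) that progressively
    destroy phylogenetic signal, compositional heterogeneity and missing-data
    structure while controlling what each scheme preserves. A sequence
    simulator with lineage-heterogeneous composition and block-structured
    missingness generates study-shaped data for validation.
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
    jsonlite,
    phangorn,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
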