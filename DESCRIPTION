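Package: divscan
Title: Differential Conservation Scanning for Multicellularity-Associated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for identifying genes associated with
    complex multicellularity in fungi by differential conservation. Implements a
    tiered -log10(e-value) filter that contrasts homology-search signal in a
    multicellular reference lineage (Pezizomycotina plus Neolecta) against two
    simplified yeast lineages, a clade-referenced tree divergence score, a
    group-differential sum-of-pairs alignment similarity profile with a
    Monte-Carlo significance band, Dollo-parsimony gene-family gain/loss
    reconstruction, and a peroxisomal targeting signal (PTS1) scanner. Ships a
    synthetic-data generator that evolves protein families on a species tree
    with clade-specific rate multipliers and gene loss, providing ground truth
    for every downstream stage, and a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
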