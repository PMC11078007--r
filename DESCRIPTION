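Package: panisles
Title: Genomic Island and Homeocassette Discovery from Prokaryotic
    Pan-Genome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers genomic islands in sets of closely related
    prokaryotic genomes by querying a pan-genome graph for runs of
    low-representation gene families flanked by core genes, classifies
    mutually exclusive island pairs that share divergent homologs
    ("homeocassettes"), and provides the supporting comparative analyses:
    total average nucleotide identity (tANI) distance phylogenies with
    fragment-resampling bootstrap, Tajima's D screening of neutral core
    genes with nested SNP-based population assignment, and
    duplication-transfer-loss (DTL) reconciliation rate comparison between
    island and core gene trees.  Includes a synthetic pan-genome generator
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
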