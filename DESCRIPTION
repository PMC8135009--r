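Package: aggnuc
Title: Nucleic-Acid Fragments and Protein Contact Networks in Insoluble
    Protein Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the nucleic-acid content and protein contact
    structure of sarkosyl-insoluble protein aggregates. Calls fragment
    pile-up peaks against a uniform genomic null with binomial/Poisson
    tail p-values, annotates peaks with nearest genes, computes two-group
    differential-abundance statistics on fragment counts (Yates
    chi-square, two-tailed Fisher exact, Welch t), screens viral read
    summaries with coverage/contiguity/count thresholds, detects and
    scores G-quadruplex-forming sequences (QGRS-style motif search,
    G4Hunter run scoring, shuffle-null fold enrichment), and classifies
    central hubs and hub connectors in crosslink-derived protein contact
    networks. Ships reference tables of aggregate-derived DNA peaks, RNA
    fragment counts and viral read summaries from Alzheimer's and
    age-matched-control hippocampus, plus seeded generators for every
    synthetic input class with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
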