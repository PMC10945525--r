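Package: terscope
Title: Bacterial Chromosome Contact-Range, Domain-Boundary and matS/Ter
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bacterial chromosome conformation and
    terminus-macrodomain genomics. Builds filtered, binned and
    SCN-balanced Hi-C/3C-seq contact maps from mapped read pairs,
    computes log2 ratio maps between conditions, quantifies the per-locus
    range of cis contacts from the width of the significant band
    perpendicular to the contact-map diagonal, calls chromosome
    interacting domain (CID) boundaries with the directional index,
    normalizes ChIP-seq coverage against input and calls
    high-fold-enrichment peaks, scans circular genomes for palindromic
    matS motifs, delimits the Ter macrodomain by the 100-kb-gap rule and
    builds dif-centered matS density profiles. A synthetic-data module
    generates contact maps with locus-dependent contact range, ChIP
    experiments with replication-following enrichment, and genomes with
    planted matS sites and programmed segment transpositions, so every
    pipeline stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
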