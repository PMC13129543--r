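Package: thermoscan
Title: Sliding-Window Thermodynamic Scanning and Consensus Modelling of
    RNA Secondary Structure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans transcript sequences with a sliding window, folding each
    window under a self-contained nearest-neighbour thermodynamic model and
    scoring it against mononucleotide- or dinucleotide-shuffled nulls to
    obtain per-window thermodynamic z-scores and ensemble diversity.
    Aggregates window predictions into z-score-weighted consensus secondary
    structures (Zsum/Znorm), extracts discrete base-paired sub-motifs with
    transcript-region assignment from GFF3 gene models, censuses structural
    elements (stems, hairpins, bulges, internal and multibranch loops), and
    writes genome-browser tracks (fixedStep WIG, BED arcs) plus standard
    structure formats (dot-bracket, connectivity tables). Includes exact
    structure-enumeration oracles and synthetic-sequence generators so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
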