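Package: clonetrace
Title: Clonal Lineage Tracing with DNA Barcodes in Xenograft Tumors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of cellular-barcoding experiments that track thousands
    of tumor clones through growth, dissemination and treatment. Provides
    demultiplexing of barcode amplicon reads into count matrices, technical
    replicate quality filters and frequency normalization, clonal statistics
    (engraftment, dispersion, biomass representation, fold-change classes,
    Shannon and Simpson diversity, cross-tissue regression), Hellinger
    distance based spatial reconstruction of cut tumors, a multinomial
    subsampling null model for shedding and seeding, a three-dimensional
    lattice simulator of barcoded tumor growth with virtual cutting, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
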