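Package: kredit
Title: Editing-Aware Analysis of Cross-Linking Tags on the Trypanosome
    Maxicircle Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing iCLIP-style UV-cross-linking tags
    (iCLAP) from mitochondrial RNA-binding proteins of Trypanosoma
    brucei against the maxicircle transcriptome, where twelve of the
    eighteen protein-coding mRNAs are remodelled by uridine
    insertion/deletion editing.  Models preedited and fully edited
    transcript pairs and per-transcript editing extent; preprocesses raw
    reads (3' adapter trimming, PCR-duplicate collapsing, 4-nt barcode
    demultiplexing); classifies each tag by sequential unique mapping to
    the maxicircle genome and then to a catenated fully-edited
    reference, using an exact ungapped seed-and-extend aligner;
    quantifies binding as per-transcript and per-category shares,
    length-normalised densities, coverage tracks, 5'-end bias, and the
    correlation of binding share with editing extent; and computes
    delta-delta-Ct fold changes, percent-of-input enrichment and
    pulldown ratios from qPCR cycle-threshold tables.  A synthetic-data
    generator emulates a maxicircle-like genome, a 3'-to-5' guide-RNA
    editing cascade and iCLIP-style read libraries with ground truth, so
    the full pipeline is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
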