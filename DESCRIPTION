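Package: umiatac
Title: UMI-Aware Deduplication, Quantification and Footprinting for ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ATAC-seq libraries that carry unique molecular
    identifiers (UMIs) ahead of the Tn5 mosaic-end sequence. Extracts UMIs
    from raw reads and trims to the mosaic-end anchor, classifies aligned
    fragments into PCR duplicates versus independent ("natural") duplicate
    Tn5 insertion events, and propagates the corrected counts through
    insertion-level quantification, Wellington-style binomial footprint
    scoring, footprint-depth computation, and a shuffle-within-peaks
    significance test for motif overlap. Includes a fully seeded simulator
    of accessibility landscapes, Tn5 fragment libraries and PCR
    amplification with a complete ground-truth ledger.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
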