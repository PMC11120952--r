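Package: pavscape
Title: Presence/Absence Variation Landscape and Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing presence/absence variations (PAVs,
    insertions and deletions of at least 50 bp) in resequenced inbred
    populations. Merges multi-caller structural-variant callsets into a
    unified presence/absence genotype matrix, applies PASS/MAF/missing-rate
    filters, summarizes the PAV size spectrum and genomic context
    (flank/CDS/UTR/intron/intergenic), detects breakpoint hotspot regions
    by sliding-window top-decile ranking, runs a principal-component
    adjusted single-locus association scan with a permutation-derived
    genome-wide significance threshold, and compares single-PAV haplotype
    groups with t-tests. Includes a synthetic-data generator emulating
    two imperfect callers over a shared truth set so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
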