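Package: poolcrispr
Title: Genotyping of Pooled CRISPR/Cas9 Mutant Libraries from Barcoded
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing pooled CRISPR/Cas9 knockout
    libraries genotyped by dual-indexed amplicon deep sequencing. Covers
    sgRNA site enumeration with an off-target mismatch filter, primer
    sub-pool partitioning and amplicon design checks, combinatorial 9-nt
    dual-index barcode design, demultiplexing of pooled reads, per-plant
    sgRNA identification from cassette amplicons, target-site editing-event
    calling with left-aligned indel normalisation and the
    edited-reads/total-reads frequency statistic, cross-generation (T0 to
    T1) heritability analysis, and a truth-tracked amplicon read simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
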