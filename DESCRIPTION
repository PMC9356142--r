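Package: editcascade
Title: Design and Evaluation of Recursive Genome-Editing Guide Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Designs SpCas9 guide-RNA cascades for Recursive Editing, an
    HDR-enhancement strategy that retargets abundant indel alleles with
    additional guides so that every error-prone repair event creates a new
    opportunity for homology-directed repair. Includes a deterministic
    microhomology/duplication indel-outcome model with adapter seams for
    external predictors, exhaustive NGG guide enumeration with on-target and
    off-target filters, a recursive search that scores and selects multi-level
    guide cascades, a mass-flow simulator of multi-round editing, scan
    pipelines over genomes, start/stop-codon annotations and variant lists,
    and a seeded synthetic fixture generator (mini-genome, GFF3, VCF) with a
    machine-readable truth table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
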