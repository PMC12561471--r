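Package: splicescan
Title: Alternative-Splicing Event Enumeration, RNA-Binding-Protein Motif
    Scanning, and PSI-Based Differential Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how an RNA-binding protein with a known
    sequence motif intersects the splicing landscape of a genome. The
    package enumerates alternative-splicing events (skipped exons,
    retained introns, mutually exclusive exons, alternative 5'/3' splice
    sites) from transcript annotations, scans genomic sequence for exact
    motif occurrences on both strands, classifies hits relative to gene
    models (exon, intron, junction-spanning, sense vs antisense),
    quantifies the fraction of each event class targeted by the motif
    within a window of its splice sites, and computes percent-spliced-in
    (PSI) and differential inclusion between conditions from junction
    read counts. A seeded synthetic-data generator emits toy genomes,
    annotations and beta-binomially dispersed count tables with known
    ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
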