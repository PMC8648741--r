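Package: gibreak
Title: Breakpoint Hotspot Statistics and Genomic Instability Survival Indexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the enrichment of structural-variant breakpoints in
    classes of genomic DNA elements (non-B DNA motifs, DNA repeats,
    regulatory elements) under a random breakage model via a binomial tail
    statistic (the Hscore), profiles hotspotness in sliding windows shifted
    by multiples of each element's length, splits element tracks by gene
    context, pools element classes into transcription-associated (iTRAC)
    and replication-associated (iRACIN) per-patient instability indexes,
    partitions cohorts against survival with an exhaustive multi-threshold
    log-rank search (iPART), and combines the index groups into the MAGIC
    high/low risk classifier.  Includes a seed-deterministic synthetic
    cohort generator (genome, annotation tracks, breakpoint catalogs,
    survival outcomes) so the whole pipeline is testable without access to
    a sequencing cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
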