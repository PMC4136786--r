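Package: ctdnaseq
Title: Error-Suppressed Detection of Circulating Tumor DNA from Deep Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying circulating tumor DNA (ctDNA)
    in deep targeted sequencing of cell-free DNA (cfDNA). Implements
    overlap merging of paired-end reads with concordance-based quality
    boosting, PCR-duplicate consensus calling that keys duplicate families
    on both start position and template length, genomic eligibility masks
    (mappability, simple repeats, germline sites), background noise-rate
    estimation with base-quality cutoff optimization, pooled one-sided
    Fisher-exact ctDNA detection, and a Monte-Carlo simulator of the
    detection limit over ctDNA fraction and DNA input mass. A synthetic
    cfDNA read generator with full ground-truth provenance makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
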