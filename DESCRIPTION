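Package: imseg
Title: Intermediate DNA Methylation Regions from Integrated MeDIP-Seq and
    MRE-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects regions of intermediate DNA methylation (IM) from
    paired MeDIP-Seq and MRE-Seq read-count tracks with a maximum scoring
    segment algorithm, calibrates score and length cutoffs against
    paired-shuffled null tracks, and assembles a multi-sample reference IM
    set. Classifies allele-specific versus allele-independent methylation
    at heterozygous SNPs with Fisher's exact test, and quantifies
    chromatin and expression associations of IM regions (binned signal
    profiles, RPKM, relative exon expression, sample distance matrices,
    CpG-level overlap enrichment). Ships a seeded synthetic-data generator
    with planted ground truth for end-to-end validation, and an 'imseg'
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
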