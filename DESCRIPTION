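Package: hetseq
Title: Heterochromatin Integrity Analysis from RIP-Chip and ChIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying the RNA targets of RNA-binding proteins
    from two-channel RIP-chip enrichment arrays (mean-centred z-scores with a
    replicate-consistency rule), calling differentially expressed genes in
    deadenylase mutants with a SAM-style moderated statistic and permutation
    false discovery rate, quantifying gene-set overlaps with expected-overlap
    and Fisher exact statistics, and measuring heterochromatin integrity as
    histone-H3-normalized H3K9 di-methylation occupancy over annotated
    islands, subtelomeres, centromeres and transposon domains from aligned
    ChIP-seq reads, with delta-delta-Ct quantification of confirmatory
    ChIP-qPCR. Includes seeded synthetic-data generators that plant known
    target sets, fold-changes and methylation domains so that every stage of
    the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rsamtools,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
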