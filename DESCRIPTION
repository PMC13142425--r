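Package: cgrscope
Title: Complex Genomic Rearrangement Analysis for Multi-Region Tumor
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("cgrscope", "developers", email = "cgrscope@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome characterization of
    genomically unstable tumors, built around a murine osteosarcoma-style
    study design. Implements coverage-based tumor purity estimation at an
    engineered biallelic-deletion locus, absolute copy-number inference
    from relative log2 ratios, blacklist filtering and 1-Mb binned
    recurrence and cosine-similarity profiles, tumor-only somatic
    consensus filtering against a panel of normals, detection of complex
    genomic rearrangements (CGRs) as clusters of interleaved structural
    variants with multi-chromosomal linkage via translocation enrichment,
    gene-level alteration calling with CGR co-occurrence flags,
    multi-region clonal phylogenetics (maximum parsimony with
    mutation-count branch lengths, UPGMA on structural variants,
    bootstrap support), and the cohort-level statistics used to compare
    mouse and human cohorts. A deterministic synthetic-cohort generator
    with known clonal structure, planted CGRs and panel-of-normals
    germline variants provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
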