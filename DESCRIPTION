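Package: cnvtriage
Title: Filtration, Prioritization and Read-Evidence Triage of Germline Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backend toolkit for clinical interpretation of germline copy
    number variants (CNVs) detected by whole-genome sequencing. Implements a
    three-step variant filtration module (problem-region containment, coding
    overlap with a non-coding exception list, population-variant containment),
    a prioritization module that annotates each CNV against population SVs,
    known pathogenic SVs, an internal cohort, dosage-sensitivity curations and
    gene models, and computes a priority score (clinical relevance plus adverse
    information) with high/moderate/low tiers, an alignment-evidence module
    that extracts binned read depth and mapping quality, depth ratios,
    insert-size outlier bounds, anomalous-read classifications and supporting
    read counts from BAM files, trio-based inheritance labelling, a
    deterministic synthetic-fixture generator (reference FASTA, aligned reads
    with engineered CNV signal, toy annotation databases), and an end-to-end
    pipeline producing ranked TSV/JSON reports for clinical review.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
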