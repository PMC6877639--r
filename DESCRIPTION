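Package: cbescan
Title: Genome-Wide Off-Target Mutation Analysis for Cytosine Base-Edited Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising unintended mutations in clones edited
    with APOBEC-based cytosine base editors, as measured by whole-genome
    sequencing against a parental line. Implements paired clone/parental
    somatic variant filtering (one-sided Fisher exact test plus read-support
    and allele-frequency thresholds), pyrimidine-normalised mutation-spectrum
    summaries and fold changes versus control clones, strand-oriented
    sequence-context extraction with position frequency matrices and
    information-content (sequence-logo) profiles, TCW-motif (APOBEC
    signature) enrichment statistics, PAM (NGG) proximity scanning with a
    sampled genomic background, intersection of variant catalogs with
    predicted CRISPR off-target sites, inter-clone overlap matrices and
    per-chromosome mutation distributions. A seeded simulator generates
    reference genomes, mutation catalogs with a planted APOBEC component and
    paired tumor/normal allele counts so the full pipeline can be exercised
    and validated against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
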