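Package: asecow
Title: Allele-Specific Expression Analysis for Bovine RNA-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting allele-specific expression
    (ASE) from paired DNA- and RNA-sequencing of a cattle cohort: DNA/RNA
    genotype concordance classification (both-homozygous, both-heterozygous,
    and the two discordant classes suggestive of RNA editing or imprinting),
    exact binomial allelic-imbalance testing of per-allele read counts at
    heterozygous-concordant sites with read-depth filtering and CNV-region
    exclusion, QTL-region annotation, linkage-disequilibrium-aware
    genotype-expression Spearman correlation with per-transcript Bonferroni
    correction, allele-specific miRNA seed-site and transcription-factor
    binding-site differencing, and pyrosequencing ASE-ratio validation
    arithmetic. A synthetic-cohort generator with configurable allelic
    imbalance, overdispersion, imprinting-like and editing-like discordance,
    linkage-disequilibrium blocks and cis-regulatory expression effects makes
    every stage runnable and testable without external data, including a
    read-mapping simulation demonstrating reference-mapping bias and its
    removal by N-masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
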