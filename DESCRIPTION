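Package: exonskip
Title: Intronic Splicing Enhancer Variants and Exon Skipping Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking intronic single-nucleotide polymorphisms to
    exon-skipping events through intronic splicing enhancer (ISE) hexamer
    motifs. Provides allele-aware motif scanning of the sequence window
    around each variant, detection of alternatively skipped (cassette)
    exons from transcript models, a Splicing Index statistic computed from
    exon-level and gene-level expression, additive-model association of
    genotype with exon skipping including Storey q-value false discovery
    control, covariate-matched permutation enrichment of SNP sets, and
    distance-to-exon distribution statistics. A synthetic-data generator
    emulates the genomic, genotypic and expression structure the analysis
    assumes so every stage can be exercised end to end without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
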