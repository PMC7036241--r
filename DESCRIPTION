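Package: neoepitopes
Title: Neoepitope Prediction from Somatic Variants with Binding, Expression
    and Cohort Recurrence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate tumor neoantigens from annotated somatic
    variants and user-supplied transcript models. Reconstructs mutant protein
    sequences (missense, inframe and frameshift effects), extracts paired
    mutant/wild-type 21-mer neoepitope windows, enumerates HLA-restricted
    k-mer peptides, scores them through a pluggable MHC binding-predictor
    adapter (a deterministic built-in predictor ships for testing), computes
    the differential agretopicity index (DAI), applies IC50 binder tiers and
    a transcripts-per-million expression filter, and aggregates per-sample
    candidates into shared-neoantigen recurrence tables, per-residue coverage
    profiles and an RNA-seq genotype-concordance benchmark. A deterministic
    synthetic-data generator produces complete reference, cohort VCF and
    abundance fixtures so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
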