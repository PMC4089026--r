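Package: aseF1
Title: Allele-Specific Expression Analysis in F1 Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Replicate-based detection of allele-specific expression (ASE)
    from RNA-seq of F1 hybrids of two inbred strains. Provides allele-specific
    read counting against an N-masked reference with reference-bias
    diagnostics, gene- and exon-level aggregation of per-SNP allele counts, a
    negative-binomial conditional exact test that treats per-allele count
    columns as replicated pseudo-samples (strain contrast for cis-eQTL,
    parent-of-origin contrast for imprinting), a per-SNP Fisher exact
    baseline, internal-consistency QC (discordant SNP/exon pairs, exclusive
    single-allele expression, premature stop-codon allelic ratios), DNase I
    hypersensitive-site intact-peak F-ratio analysis, and cis- versus
    local-eQTL set comparisons. A synthetic-data module generates toy
    genomes, variants, allele-count tables and aligned reads with the full
    effect taxonomy (cis effects, imprinting, sex specificity, global
    mapping bias, genotyping-error loci) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    XVector,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
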