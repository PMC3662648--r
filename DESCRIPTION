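Package: pikapool
Title: Pooled-Transcriptome SNP Discovery and Elevation Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering single-nucleotide polymorphisms from pooled
    transcriptome sequencing of two populations and scoring their
    allele-frequency divergence. Implements quality trimming of reads with
    per-base error probabilities (modified-Mott segment selection),
    ungapped seed-and-extend read mapping under identity and length-fraction
    acceptance rules, per-pool pileup construction, threshold-based SNP
    calling within each pool, cross-pool merging into polymorphic/fixed
    categories with a major-allele divergence index, contig-level coverage
    filters and redundancy classification, candidate-panel selection,
    validation-panel population statistics (heterozygosities, exact
    Hardy-Weinberg tests, permutation tests of linkage disequilibrium,
    Holm correction), closed-form and simulated small-pool apparent-fixation
    probabilities, and synonymous/non-synonymous classification of coding
    substitutions under the standard or vertebrate mitochondrial genetic
    code. A synthetic-data module generates reference transcripts, diploid
    pool genotypes, pooled reads with qualities, and biallelic genotype
    panels with full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
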