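#!/usr/bin/env Rscript
# Stage 1: build the synthetic two-pool benchmark.
#
# Two populations of three diploid pikas each, sampled as pooled RNA
# libraries: 200 reference transcripts of ~1 kb, variable sites at 0.005
# per base with per-pool allele frequencies drawn uniformly (2% of sites
# fixed for alternate alleles), 30x pooled reads per population with the
# read-length means of the two real libraries (266.8 / 245.7 bases), 0.5%
# substitution errors, Q30 correct bases and Q10-30 errors.
# Outputs: FASTA + two FASTQs + truth-table TSV under scratch/benchmark/,
# resolved models under results/.

library(pikapool)

seed <- 20919L
dir.create("scratch/benchmark", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

bm <- benchmark_dataset(seed = seed)

write_reference(bm$reference, "scratch/benchmark/reference.fasta")
write_fastq(bm$reads$high, "scratch/benchmark/high.fastq")
write_fastq(bm$reads$low, "scratch/benchmark/low.fastq")
write_truth_table(bm$truth, "scratch/benchmark/truth_sites.tsv")
write_model_config(bm$popmodel, bm$seqmodel, "results/benchmark_models.json")

s <- bm$truth$sites
message(sprintf("reference: %d transcripts, %d bases",
                length(bm$reference), sum(Biostrings::width(bm$reference))))
message(sprintf("truth: %d variable sites (%d fixed-different)",
                nrow(s), sum(s$fixed_different)))
message(sprintf("reads: high %d, low %d (%.1f / %.1f Mb)",
                nrow(bm$reads$high), nrow(bm$reads$low),
                sum(nchar(bm$reads$high$seq)) / 1e6,
                sum(nchar(bm$reads$low$seq)) / 1e6))
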