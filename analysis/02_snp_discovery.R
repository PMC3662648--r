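#!/usr/bin/env Rscript
# Stage 2: run the discovery pipeline on the stage-1 benchmark — trim,
# map, pileup, contig filters, per-pool SNP calls, cross-pool
# classification, divergence/Ts-Tv accounting, candidate panel — and keep
# the summary tables under results/ (bulky per-read/per-site tables stay
# in scratch/pipeline/).

library(pikapool)

stopifnot(file.exists("scratch/benchmark/reference.fasta"))
cfg <- pipeline_config(reference = "scratch/benchmark/reference.fasta",
                       reads_high = "scratch/benchmark/high.fastq",
                       reads_low = "scratch/benchmark/low.fastq",
                       out_dir = "scratch/pipeline",
                       seed = 20919L)
res <- run_pipeline(cfg)

dir.create("results", showWarnings = FALSE)
file.copy(file.path("scratch/pipeline",
                    c("read_summary.tsv", "contig_summary.tsv",
                      "summary.json", "panel.tsv")),
          "results", overwrite = TRUE)

sm <- res$summary
message(sprintf("high-coverage contigs: %d of %d", sm$n_high_coverage,
                sm$n_contigs))
message(sprintf("merged SNPs: %d (a=%d, b=%d, c=%d, undetermined=%d)",
                sm$n_snps_total, sm$categories$a, sm$categories$b,
                sm$categories$c, sm$categories$undetermined))
message(sprintf("Ts/Tv = %.2f; mean divergence = %.1f%%; panel candidates = %d",
                sm$tstv$ratio, 100 * sm$mean_divergence, sm$n_panel))

# redundancy classes of the retained contigs (all should be unique for
# independently drawn random transcripts)
red <- cluster_redundant_contigs(read_reference("scratch/benchmark/reference.fasta"))
message(sprintf("redundancy: %d unique, %d one-partner, %d multi-partner",
                sum(red$class == "unique"), sum(red$class == "one_partner"),
                sum(red$class == "multi_partner")))
data.table::fwrite(red, "results/contig_redundancy.tsv", sep = "\t")
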