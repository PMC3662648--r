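#!/usr/bin/env Rscript
# Stage 5: coding-substitution characterization of a mitochondrial-style
# gene. The two haplotypes here are SYNTHETIC stand-ins for an
# elevation-associated NADH-dehydrogenase-subunit haplotype pair: a
# 30-codon coding region carrying eight substitutions, three of which
# change the amino acid under the vertebrate mitochondrial code.

library(pikapool)

base <- c("CTA", "GGC", "TCA", "ACC", "GTA", "GCC", "CGA", "TTC",
          "CAC", "AAA", "ATT", "GAC", "CCA", "TGC", "AGC", "CTT",
          "GGG", "TCC", "ACA", "GTG", "GCT", "CGG", "TTT", "CAT",
          "AAG", "ATC", "GAT", "CCC", "TGT", "ATG")
alt <- base
alt[c(1, 3, 5, 7, 9)] <- c("CTG", "TCG", "GTG", "CGG", "CAT")  # synonymous
alt[c(10, 12, 14)] <- c("GAA", "AAC", "TGG")                   # non-synonymous
hap_high <- paste(base, collapse = "")
hap_low <- paste(alt, collapse = "")

recs <- classify_codon_substitutions(hap_high, hap_low,
                                     code = "vertebrate_mitochondrial")
dir.create("results", showWarnings = FALSE)
data.table::fwrite(recs, "results/coding_substitutions.tsv", sep = "\t")

message(sprintf("polymorphic sites: %d, non-synonymous: %d",
                attr(recs, "n_sites"), attr(recs, "n_nonsynonymous")))
message(sprintf("high-haplotype translation: %s",
                translate_cds(hap_high, code = "vertebrate_mitochondrial")))
message(sprintf("low-haplotype translation:  %s",
                translate_cds(hap_low, code = "vertebrate_mitochondrial")))
print(recs[, c("pos", "codon_index", "codon_a", "codon_b", "aa_a", "aa_b",
               "class", "tstv")])
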