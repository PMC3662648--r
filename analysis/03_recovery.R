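#!/usr/bin/env Rscript
# Stage 3: score the pipeline against the simulator's ground truth —
# per-minor-frequency detection of pool-polymorphic sites, false calls at
# invariant columns, and agreement of called frequencies with the realized
# pool frequencies.

library(pikapool)
library(data.table)

bm <- benchmark_dataset(seed = 20919L)
reads <- rbindlist(lapply(bm$reads, trim_read_set))
pl <- map_reads(reads, reference_index(bm$reference))
pu <- build_pileups(pl, reads, bm$reference)
pol <- calling_policy()
ch <- call_group_snps(pu, "high", pol)
cl <- call_group_snps(pu, "low", pol)

dq <- pileup_depth(pu, pol$min_base_quality)
dw <- dcast(dq, contig + pos ~ pool, value.var = "depth", fill = 0L)
tt <- merge(bm$truth$sites, dw, by = c("contig", "pos"), all.x = TRUE)
tt[is.na(high), high := 0L][is.na(low), low := 0L]
tt <- merge(tt, unique(ch[, .(contig, pos)])[, called_h := TRUE],
            by = c("contig", "pos"), all.x = TRUE)
tt <- merge(tt, unique(cl[, .(contig, pos)])[, called_l := TRUE],
            by = c("contig", "pos"), all.x = TRUE)
tt[is.na(called_h), called_h := FALSE][is.na(called_l), called_l := FALSE]

both_deep <- tt$high >= pol$min_coverage & tt$low >= pol$min_coverage
rows <- list()
for (p in c("high", "low")) {
  f <- tt[[paste0("pool_freq_", p)]]
  called <- tt[[if (p == "high") "called_h" else "called_l"]]
  qual <- f > 0 & f < 1 & both_deep
  minor <- pmin(tt[[paste0("alt_count_", p)]],
                6L - tt[[paste0("alt_count_", p)]])
  for (k in 1:3) {
    sel <- qual & minor == k
    rows[[length(rows) + 1L]] <- data.table(
      pool = p, minor_chromosomes = k, n_sites = sum(sel),
      detection = mean(called[sel]))
  }
  rows[[length(rows) + 1L]] <- data.table(pool = p, minor_chromosomes = NA,
                                          n_sites = sum(qual),
                                          detection = mean(called[qual]))
}
recov <- rbindlist(rows)
dir.create("results", showWarnings = FALSE)
fwrite(recov, "results/recovery.tsv", sep = "\t")

overall <- recov[is.na(minor_chromosomes),
                 sum(detection * n_sites) / sum(n_sites)]
message(sprintf("overall detection of qualifying pool-polymorphic sites: %.1f%%",
                100 * overall))
message("per-stratum detection (minor chromosomes of 6):")
print(recov[!is.na(minor_chromosomes)])

called_sites <- unique(rbindlist(list(ch[, .(contig, pos)],
                                      cl[, .(contig, pos)])))
fp <- called_sites[!bm$truth$sites[, .(contig, pos)], on = c("contig", "pos")]
n_inv <- sum(nchar(as.character(bm$reference))) - nrow(bm$truth$sites)
message(sprintf("false calls at invariant columns: %d / %d (%.2e)",
                nrow(fp), n_inv, nrow(fp) / n_inv))
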