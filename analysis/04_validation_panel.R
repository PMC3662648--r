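#!/usr/bin/env Rscript
# Stage 4: validation-panel statistics in the shape of a genotyping
# follow-up — 17 biallelic loci typed in four site-by-elevation groups
# (10/11/10/11 individuals), per-group Ho/He, exact Hardy-Weinberg tests
# with Holm correction, pairwise linkage-disequilibrium permutation tests,
# and the small-pool apparent-fixation analysis that explains why so many
# discovery-panel SNPs look fixed at one elevation.

library(pikapool)
library(data.table)

panel <- simulate_validation_panel(n_loci = 17L, seed = 20919L)
st <- panel_statistics(panel)
dir.create("results", showWarnings = FALSE)
fwrite(st, "results/panel_statistics.tsv", sep = "\t")
message(sprintf("panel: %d locus-group cells; %d monomorphic; %d HWE rejections after Holm",
                nrow(st), sum(st$monomorphic), sum(st$hwe_reject)))

# pairwise LD within each group (first 8 loci to keep the table short)
loci <- head(unique(panel$locus), 8)
ld_rows <- list()
for (g in unique(panel$group)) {
  sub <- panel[group == g]
  wide <- dcast(sub, individual ~ locus, value.var = "genotype")
  for (i in seq_along(loci)) for (j in seq_len(i - 1L)) {
    out <- ld_permutation_test(wide[[loci[i]]], wide[[loci[j]]],
                               n_permutations = 999L,
                               seed = 20919L + 13L * i + j)
    ld_rows[[length(ld_rows) + 1L]] <- data.table(
      group = g, locus1 = loci[j], locus2 = loci[i],
      testable = out$testable, G = out$G, p = out$p)
  }
}
ld <- rbindlist(ld_rows)
ld[testable == TRUE, reject := holm_correction(p, 0.05)]
fwrite(ld, "results/ld_tests.tsv", sep = "\t")
message(sprintf("LD: %d testable pairs, %d significant after Holm",
                sum(ld$testable), sum(ld$reject, na.rm = TRUE)))

# apparent fixation in an n = 3 pool across population frequencies
grid <- data.table(q = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5))
grid[, closed_form := apparent_fixation_probability(q, 3)]
grid[, simulated := vapply(q, function(qq)
  simulate_apparent_fixation(qq, 3, n_sites = 10000,
                             seed = 20919L)$rate, numeric(1))]
grid[, simulated_30x := vapply(q, function(qq)
  simulate_apparent_fixation(qq, 3, n_sites = 10000, depth = 30,
                             seed = 20919L)$rate, numeric(1))]
fwrite(grid, "results/apparent_fixation.tsv", sep = "\t")
message("apparent-fixation probability (pool of 3 diploids):")
print(grid)
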