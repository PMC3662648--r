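test_that("reference generation is deterministic, sized, and degenerate-safe", {
  a <- generate_reference(10, length_mean = 500, length_sd = 100, seed = 7)
  b <- generate_reference(10, length_mean = 500, length_sd = 100, seed = 7)
  expect_identical(as.character(a), as.character(b))

  big <- generate_reference(200, length_mean = 1000, length_sd = 100, seed = 2)
  expect_length(big, 200)
  expect_lt(abs(mean(Biostrings::width(big)) - 1000) / 1000, 0.05)
  expect_true(all(grepl("^[ACGT]+$", as.character(big))))

  fixed <- generate_reference(5, length_mean = 300, length_sd = 0, seed = 3)
  expect_true(all(Biostrings::width(fixed) == 300))

  expect_error(generate_reference(0), ">= 1")
})

test_that("pool genotypes honor fixed and zero frequencies", {
  ref <- generate_reference(4, length_mean = 600, length_sd = 0, seed = 9)
  pm <- population_model(variable_site_density = 0.02,
                         prop_fixed_different = 1, seed = 9)
  truth <- simulate_pool_genotypes(pm, ref)
  s <- truth$sites
  expect_true(all(s$pool_freq_high %in% c(0, 1)))
  expect_true(all(s$pool_freq_low == 1 - s$pool_freq_high))

  # f_high = 0 everywhere: every high-pool genotype homozygous reference
  pm0 <- population_model(variable_site_density = 0.02,
                          prop_fixed_different = 0,
                          freq_fun = function(n) rep(0, n), seed = 4)
  t0 <- simulate_pool_genotypes(pm0, ref)
  gt_cols <- grep("^gt_high_", names(t0$sites), value = TRUE)
  expect_true(all(t0$sites[, unlist(.SD), .SDcols = gt_cols] == 0L))
})

test_that("realized pool frequencies are binomial draws from the population frequency", {
  ref <- generate_reference(1, length_mean = 40000, length_sd = 0, seed = 5)
  pm <- population_model(variable_site_density = 0.25,
                         prop_fixed_different = 0,
                         freq_fun = function(n) rep(0.3, n), seed = 5)
  truth <- simulate_pool_genotypes(pm, ref)
  m <- nrow(truth$sites)
  expect_gt(m, 5000)
  se <- sqrt(0.3 * 0.7 / (6 * m))
  expect_lt(abs(mean(truth$sites$pool_freq_high) - 0.3), 3 * se)
  # chromosome counts and genotypes agree
  expect_identical(truth$sites$alt_count_high,
                   rowSums(truth$sites[, .(gt_high_1, gt_high_2, gt_high_3)]))
})

test_that("error-free reads are exact substrings of their source haplotypes", {
  bm <- tiny_benchmark(seed = 13, n_transcripts = 3, depth = 6)
  sm0 <- sequencing_model(mean_depth_per_pool = 6,
                          substitution_error_rate = 0, seed = 13)
  reads <- simulate_pooled_reads(bm$truth, sm0)
  h <- bm$truth$haplotypes
  for (i in seq_len(min(150, nrow(reads$low)))) {
    f <- strsplit(reads$low$id[i], ":", fixed = TRUE)[[1]]
    ind <- as.integer(sub("ind(\\d+)\\.hap\\d+", "\\1", f[4]))
    hp <- as.integer(sub("ind\\d+\\.hap(\\d+)", "\\1", f[4]))
    src <- h[h$pool == "low" & h$individual == ind & h$hap == hp &
             h$contig == f[2], ]$seq
    st <- as.integer(f[3])
    expect_identical(substr(src, st, st + nchar(reads$low$seq[i]) - 1L),
                     reads$low$seq[i])
  }
})

test_that("emitted bases track the target depth and reads are reproducible", {
  ref <- generate_reference(10, length_mean = 1000, length_sd = 0, seed = 21)
  pm <- population_model(variable_site_density = 0.005, seed = 21)
  truth <- simulate_pool_genotypes(pm, ref)
  sm <- sequencing_model(mean_depth_per_pool = 30, seed = 21)
  reads <- simulate_pooled_reads(truth, sm)
  for (p in c("high", "low")) {
    emitted <- sum(nchar(reads[[p]]$seq))
    expect_lt(abs(emitted - 30 * 10000) / (30 * 10000), 0.10)
  }
  again <- simulate_pooled_reads(truth, sm)
  expect_identical(reads$high$seq, again$high$seq)
  expect_identical(reads$low$qual, again$low$qual)
})

test_that("pooled read alleles at a site follow the realized pool frequency", {
  # one contig, many half-frequency sites: alt-read fraction ~ Binomial mean
  ref <- generate_reference(1, length_mean = 30000, length_sd = 0, seed = 31)
  pm <- population_model(variable_site_density = 0.03,
                         prop_fixed_different = 0,
                         freq_fun = function(n) rep(0.5, n), seed = 31)
  truth <- simulate_pool_genotypes(pm, ref)
  sm <- sequencing_model(mean_depth_per_pool = 30,
                         substitution_error_rate = 0, seed = 31)
  reads <- simulate_pooled_reads(truth, sm)
  idx <- reference_index(ref)
  pl <- map_reads(reads$high, idx)
  pu <- build_pileups(pl, reads$high, ref)
  s <- bm_site_fracs <- merge(
    pu[, .(n = sum(n)), by = .(contig, pos, base)],
    truth$sites[, .(contig, pos, ref, alt, pool_freq_high)],
    by = c("contig", "pos"))
  alt_frac <- s[, .(frac = sum(n[base == alt]) / sum(n),
                    f = pool_freq_high[1]), by = pos]
  # realized pool frequencies are themselves binomial; compare against them
  expect_gt(nrow(alt_frac), 300)
  expect_lt(abs(mean(alt_frac$frac - alt_frac$f)), 0.02)
})

test_that("genotype panels respect inbreeding bounds and HWE expectations", {
  expect_true(all(simulate_genotype_panel(0.5, 500, inbreeding_f = 1,
                                          seed = 2) != "Aa"))
  expect_true(all(simulate_genotype_panel(0, 50, seed = 3) == "aa"))
  g <- simulate_genotype_panel(0.5, 10000, inbreeding_f = 0, seed = 4)
  het <- mean(g == "Aa")
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
  expect_identical(simulate_genotype_panel(0.3, 20, seed = 9),
                   simulate_genotype_panel(0.3, 20, seed = 9))
  expect_error(simulate_genotype_panel(1.2, 10), "\\[0,1\\]")
})

test_that("simulated validation panels carry the requested group structure", {
  panel <- simulate_validation_panel(n_loci = 4, seed = 6)
  expect_setequal(unique(panel$group), c("BC_high", "BC_low", "OR_high", "OR_low"))
  expect_identical(nrow(panel), 4L * (10L + 11L + 10L + 11L))
  expect_true(all(panel$genotype %in% c("AA", "Aa", "aa")))
})
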