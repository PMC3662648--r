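test_that("a column passing all four thresholds yields a call with correct frequencies", {
  pu <- make_pileup(list("tigA", 50, "high", "A", 30, 8),
                    list("tigA", 50, "high", "G", 30, 2))
  calls <- call_group_snps(pu, "high")
  expect_identical(nrow(calls), 2L)
  expect_identical(calls[calls$allele == "G", ]$freq, 0.20)
  expect_identical(calls[calls$allele == "A", ]$freq, 0.80)
  expect_identical(unique(calls$depth), 10L)
})

test_that("columns failing coverage, allele-count, or quality thresholds are non-calls", {
  # depth 7 < 8
  p1 <- make_pileup(list("tigA", 10, "high", "A", 30, 5),
                    list("tigA", 10, "high", "G", 30, 2))
  expect_identical(nrow(call_group_snps(p1, "high")), 0L)
  # single variant read
  p2 <- make_pileup(list("tigA", 10, "high", "A", 30, 9),
                    list("tigA", 10, "high", "G", 30, 1))
  expect_identical(nrow(call_group_snps(p2, "high")), 0L)
  # variant reads below base quality
  p3 <- make_pileup(list("tigA", 10, "high", "A", 30, 18),
                    list("tigA", 10, "high", "G", 10, 2))
  expect_identical(nrow(call_group_snps(p3, "high")), 0L)
  # variant frequency below 10%
  p4 <- make_pileup(list("tigA", 10, "high", "A", 30, 28),
                    list("tigA", 10, "high", "G", 30, 2))
  expect_identical(nrow(call_group_snps(p4, "high")), 0L)
})

test_that("the caller matches a brute-force threshold checker on random columns", {
  set.seed(99)
  pol <- calling_policy()
  n_cols <- 800
  rows <- list()
  expected <- vector("list", n_cols)
  for (i in seq_len(n_cols)) {
    depth <- sample(1:25, 1)
    bases <- sample(c("A", "C", "G", "T"), depth, TRUE,
                    prob = c(0.45, 0.3, 0.15, 0.1))
    quals <- sample(c(10L, 19L, 20L, 30L, 40L), depth, TRUE)
    expected[[i]] <- caller_brute(bases, quals, pol)
    tab <- data.table::data.table(base = bases, qual = quals)
    agg <- tab[, .N, by = .(base, qual)]
    for (r in seq_len(nrow(agg)))
      rows[[length(rows) + 1L]] <- list("tigA", i, "high", agg$base[r],
                                        agg$qual[r], agg$N[r])
  }
  pu <- do.call(make_pileup, rows)
  calls <- call_group_snps(pu, "high", pol)
  got <- split(calls$allele, calls$pos)
  for (i in seq_len(n_cols)) {
    exp_alleles <- expected[[i]]
    if (is.null(exp_alleles)) {
      expect_false(as.character(i) %in% names(got), info = paste("col", i))
    } else {
      expect_identical(sort(got[[as.character(i)]]), exp_alleles,
                       info = paste("col", i))
    }
  }
})

test_that("cross-pool classification assigns the three categories and undetermined", {
  pu <- make_pileup(
    # site 100: polymorphic both -> a
    list("tigA", 100, "high", "A", 30, 8), list("tigA", 100, "high", "G", 30, 4),
    list("tigA", 100, "low", "A", 30, 6), list("tigA", 100, "low", "G", 30, 6),
    # site 200: polymorphic high, low fixed A at depth 12 -> b
    list("tigA", 200, "high", "A", 30, 7), list("tigA", 200, "high", "G", 30, 3),
    list("tigA", 200, "low", "A", 30, 12),
    # site 300: high all G depth 15, low all A depth 20 -> c
    list("tigA", 300, "high", "G", 30, 15),
    list("tigA", 300, "low", "A", 30, 20),
    # site 400: polymorphic high, low depth 5 -> undetermined
    list("tigA", 400, "high", "A", 30, 9), list("tigA", 400, "high", "G", 30, 5),
    list("tigA", 400, "low", "A", 30, 5))
  ch <- call_group_snps(pu, "high")
  cl <- call_group_snps(pu, "low")
  m <- merge_and_classify(ch, cl, pu)
  expect_identical(m[m$pos == 100, ]$category, "a")
  expect_identical(m[m$pos == 200, ]$category, "b")
  expect_identical(m[m$pos == 300, ]$category, "c")
  expect_identical(m[m$pos == 400, ]$category, "undetermined")
  expect_identical(m[m$pos == 300, ]$divergence, 1)
  expect_equal(m[m$pos == 200, ]$divergence, 0.3, tolerance = 1e-12)
  expect_true(is.na(m[m$pos == 400, ]$divergence))
  # partition identity
  expect_identical(nrow(m), sum(m$category %in% c("a", "b", "c", "undetermined")))
})

test_that("divergence uses the combined-pool major allele with lexicographic ties", {
  expect_equal(divergence_index(c(A = 9, G = 1), c(A = 6, G = 4)), 0.3)
  expect_equal(divergence_index(c(G = 15), c(A = 20)), 1.0)
  expect_equal(divergence_index(c(A = 5, G = 5), c(A = 5, G = 5)), 0)
  # tie in combined counts -> lexicographically first allele (A)
  expect_equal(divergence_index(c(A = 6, C = 4), c(A = 4, C = 6)), 0.2)
  expect_error(divergence_index(c(A = 3, C = 3, G = 4), c(A = 10)), "biallelic")
})

test_that("transition/transversion classes and ratio follow the purine/pyrimidine rule", {
  recs <- data.table::data.table(
    category = "a",
    subst_class = c("transition", "transition", "transversion"))
  tv <- transition_transversion(recs)
  expect_identical(tv$n_transitions, 2L)
  expect_identical(tv$ratio, 2)
  # class assignment inside merge_and_classify
  pu <- make_pileup(
    list("tigA", 10, "high", "A", 30, 6), list("tigA", 10, "high", "G", 30, 6),
    list("tigA", 10, "low", "A", 30, 6), list("tigA", 10, "low", "G", 30, 6),
    list("tigA", 20, "high", "A", 30, 6), list("tigA", 20, "high", "T", 30, 6),
    list("tigA", 20, "low", "A", 30, 6), list("tigA", 20, "low", "T", 30, 6))
  m <- merge_and_classify(call_group_snps(pu, "high"),
                          call_group_snps(pu, "low"), pu)
  expect_identical(m[m$pos == 10, ]$subst_class, "transition")
  expect_identical(m[m$pos == 20, ]$subst_class, "transversion")
  # no transversions -> flagged undefined
  expect_true(is.na(transition_transversion(
    data.table::data.table(subst_class = "transition"))$ratio))
})

test_that("candidate-panel selection enforces divergence, bounds, and isolation", {
  rec <- data.table::data.table(
    contig = "tigA",
    pos = c(500L, 700L, 740L, 60L, 900L),
    category = "a",
    divergence = c(0.62, 0.80, 0.55, 0.9, 0.45),
    n_alleles = 2L)
  panel <- select_candidate_panel(rec, c(tigA = 1000L),
                                  divergence_threshold = 0.5,
                                  amplicon_length = 200L)
  # 500: isolated, selected; 700/740: mutual neighbors excluded;
  # 60: window leaves the contig; 900: below threshold
  expect_identical(panel$pos, 500L)
  expect_identical(panel$window_start, 400L)
  expect_identical(panel$window_end, 599L)
})

test_that("category counts always partition the merged table on synthetic runs", {
  bm <- tiny_benchmark(seed = 47, n_transcripts = 5, depth = 20)
  reads <- data.table::rbindlist(lapply(bm$reads, trim_read_set))
  pl <- map_reads(reads, reference_index(bm$reference))
  pu <- build_pileups(pl, reads, bm$reference)
  m <- merge_and_classify(call_group_snps(pu, "high"),
                          call_group_snps(pu, "low"), pu)
  tab <- table(factor(m$category, c("a", "b", "c", "undetermined")))
  expect_identical(sum(tab), nrow(m))
  expect_true(all(m$divergence >= 0 & m$divergence <= 1, na.rm = TRUE))
  # D = 1 exactly for category c, and only there among biallelic sites
  expect_true(all(m[m$category == "c", ]$divergence == 1))
  expect_true(all(m[m$category != "c" & !is.na(m$divergence), ]$divergence < 1 + 1e-12))
})
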