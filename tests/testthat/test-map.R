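make_ref <- function(seed = 3, n = 2, len = 1500) {
  generate_reference(n, length_mean = len, length_sd = 0, seed = seed)
}

test_that("an exact substring maps at full identity and fraction", {
  ref <- make_ref()
  rseq <- substr(as.character(ref[[1]]), 1001, 1250)
  pl <- map_read(rseq, ref)
  expect_identical(pl$contig, "tig000001")
  expect_identical(pl$start, 1001L)
  expect_identical(pl$identity, 1)
  expect_identical(pl$fraction, 1)
  expect_false(pl$ambiguous)
})

test_that("alignments below the similarity threshold are rejected", {
  ref <- make_ref()
  rseq <- substr(as.character(ref[[1]]), 101, 200)
  # 15 mismatches in 100 bases -> identity 0.85; leave a clean seed window
  mut <- strsplit(rseq, "")[[1]]
  at <- seq(41, 97, by = 4)[1:15]
  mut[at] <- vapply(mut[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
  expect_null(map_read(paste(mut, collapse = ""), ref))
  # 9 mismatches -> identity 0.91 passes
  mut2 <- strsplit(rseq, "")[[1]]
  mut2[at[1:9]] <- vapply(mut2[at[1:9]], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  pl <- map_read(paste(mut2, collapse = ""), ref)
  expect_identical(pl$identity, 0.91)
})

test_that("alignments covering too little of the read are rejected", {
  ref <- make_ref()
  rc <- as.character(ref[[1]])
  # read overhangs the contig end: only 40 of 100 bases alignable
  tail40 <- substr(rc, nchar(rc) - 39, nchar(rc))
  junk <- paste(rep("A", 60), collapse = "")
  read40 <- paste0(tail40, junk)
  expect_null(map_read(read40, ref))
  # 60 alignable bases at identity 1 -> fraction 0.6 passes
  tail60 <- substr(rc, nchar(rc) - 59, nchar(rc))
  read60 <- paste0(tail60, paste(rep("A", 40), collapse = ""))
  pl <- map_read(read60, ref)
  expect_identical(pl$span, 60L)
  expect_identical(pl$fraction, 0.6)
})

test_that("reverse-complement reads map to the same origin on the minus strand", {
  ref <- make_ref()
  rseq <- substr(as.character(ref[[2]]), 501, 700)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rseq)))
  pl <- map_read(rc, ref)
  expect_identical(pl$contig, "tig000002")
  expect_identical(pl$start, 501L)
  expect_identical(pl$strand, "-")
})

test_that("reads matching two contigs equally are flagged ambiguous", {
  dup <- Biostrings::DNAStringSet(c(a_tig = "ACGTACGTACGTTGCACGGATCGATCGGATCCTAGCTAGGCTAGCTAGGA",
                                    b_tig = "ACGTACGTACGTTGCACGGATCGATCGGATCCTAGCTAGGCTAGCTAGGA"))
  pl <- map_read(substr(as.character(dup[[1]]), 1, 40), dup,
                 mapping_policy(seed_length = 10L))
  expect_true(pl$ambiguous)
  expect_identical(pl$contig, "a_tig")  # lowest (contig, position) reported
})

test_that("simulated error-free reads map back to their true origins", {
  bm <- tiny_benchmark(seed = 17, n_transcripts = 5, depth = 10)
  sm0 <- sequencing_model(mean_depth_per_pool = 10,
                          substitution_error_rate = 0, seed = 17)
  reads <- simulate_pooled_reads(bm$truth, sm0)
  idx <- reference_index(bm$reference)
  for (p in c("high", "low")) {
    pl <- map_reads(reads[[p]], idx)
    tags <- data.table::tstrsplit(pl$id, ":", fixed = TRUE)
    agree <- pl$contig == tags[[2]] & pl$start == as.integer(tags[[3]])
    expect_gte(mean(agree), 0.99)
    expect_gte(nrow(pl) / nrow(reads[[p]]), 0.99)
  }
})

test_that("pileup columns conserve depth and match an interval-counting oracle", {
  bm <- tiny_benchmark(seed = 11, n_transcripts = 3, depth = 12)
  reads <- data.table::rbindlist(bm$reads)
  pl <- map_reads(reads, reference_index(bm$reference))
  pu <- build_pileups(pl, reads, bm$reference)

  # per-pool depths sum to combined depth
  d <- pileup_depth(pu)
  comb <- d[, .(total = sum(depth)), by = .(contig, pos)]
  dall <- pu[, .(total = sum(n)), by = .(contig, pos)]
  expect_identical(comb[order(contig, pos)]$total, dall[order(contig, pos)]$total)

  # independent coverage oracle (IRanges) per contig
  acc <- pl[pl$ambiguous == FALSE, ]
  for (tg in unique(acc$contig)) {
    rows <- acc[acc$contig == tg, ]
    cov <- IRanges::coverage(IRanges::IRanges(rows$start,
                                              width = rows$span))
    got <- dall[contig == tg][order(pos)]
    expected <- as.integer(cov)[got$pos]
    expect_identical(got$total, expected)
    # no column exceeds the number of accepted overlapping placements
    expect_true(all(got$total <= nrow(rows)))
  }
})

test_that("two identical error-free reads give depth two and one allele", {
  ref <- make_ref(seed = 5, n = 1, len = 400)
  rseq <- substr(as.character(ref[[1]]), 1, 100)
  q <- intToUtf8(rep(63L, 100))
  reads <- read_set(c("a", "b"), c(rseq, rseq), c(q, q), pool = "high")
  pl <- map_reads(reads, ref)
  pu <- build_pileups(pl, reads, ref)
  d <- pileup_depth(pu)
  expect_true(all(d$depth == 2L))
  expect_identical(nrow(pu), 100L)  # one (base, qual) row per column
})

test_that("SAM round trip preserves placements and rejects threshold failures", {
  ref <- make_ref(seed = 19, n = 2, len = 800)
  bm <- tiny_benchmark(seed = 19, n_transcripts = 2, depth = 6)
  reads <- data.table::rbindlist(bm$reads)
  pl <- map_reads(reads, reference_index(bm$reference))
  sam <- tempfile(fileext = ".sam")
  write_sam(pl, reads, bm$reference, sam)
  ing <- ingest_alignments(sam, bm$reference)
  expect_identical(nrow(ing$placements), nrow(pl))
  m <- merge(as.data.frame(pl)[c("id", "contig", "start", "identity")],
             as.data.frame(ing$placements)[c("id", "contig", "start", "identity")],
             by = "id")
  expect_true(all(m$contig.x == m$contig.y))
  expect_true(all(m$start.x == m$start.y))
  expect_equal(m$identity.x, m$identity.y, tolerance = 1e-12)

  # hand-built records: pass, unmapped, and identity 0.85 reject
  rc <- as.character(bm$reference)
  good <- substr(rc[[1]], 11, 110)
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(rc), nchar(rc)),
             paste("high:r1", 0L, names(rc)[1], 11L, 60L, "100M", "*", 0L, 0L,
                   good, intToUtf8(rep(63L, 100)), "NM:i:0", sep = "\t"),
             paste("high:r2", 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   good, intToUtf8(rep(63L, 100)), sep = "\t"),
             paste("high:r3", 0L, names(rc)[1], 11L, 60L, "100M", "*", 0L, 0L,
                   good, intToUtf8(rep(63L, 100)), "NM:i:15", sep = "\t"))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(lines, sam2)
  ing2 <- ingest_alignments(sam2, bm$reference)
  expect_identical(nrow(ing2$placements), 1L)
  expect_identical(ing2$placements$id, "high:r1")
  expect_identical(unname(ing2$log["unmapped"]), 1L)
  expect_identical(unname(ing2$log["rejected"]), 1L)
})

test_that("SAM records for unknown contigs are an error", {
  ref <- make_ref(seed = 23, n = 1, len = 300)
  rc <- as.character(ref)
  lines <- c(sprintf("@SQ\tSN:%s\tLN:%d", "other", 300L),
             paste("r1", 0L, "other", 1L, 60L, "50M", "*", 0L, 0L,
                   substr(rc[[1]], 1, 50), intToUtf8(rep(63L, 50)),
                   "NM:i:0", sep = "\t"))
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  expect_error(ingest_alignments(sam, ref), "absent from the reference")
})
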