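# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or direct enumeration, never by calling the
# package's own code path.

# exhaustive best-segment search: all O(L^2) contiguous substrings,
# leftmost start first, then longest, among maximal sums
mott_brute <- function(p, limit) {
  L <- length(p)
  s <- limit - p
  best <- 0
  best_seg <- c(start = 0L, end = 0L)
  for (i in seq_len(L)) {
    run <- 0
    for (j in i:L) {
      run <- run + s[j]
      if (run > best + 1e-12) {
        best <- run
        best_seg <- c(start = i, end = j)
      } else if (abs(run - best) <= 1e-12 && best_seg[1] == i &&
                 j > best_seg[2]) {
        # same-sum extension of the already-chosen leftmost segment
        best_seg[2] <- j
      }
    }
  }
  if (best <= 1e-12) c(start = 0L, end = 0L) else best_seg
}

# conditional HWE enumeration by direct counting: P(h) is the number of
# ways to arrange the alleles into genotypes over the number of ways to
# choose which chromosomes carry A
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hs <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2L)
  prob <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    cc <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(cc)) *
      2^h / choose(2 * n, nA)
  }, numeric(1))
  obs <- prob[match(n_Aa, hs)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# brute-force per-column SNP-call check: operates on one column's raw
# (base, qual) multiset with explicit loops over the thresholds
caller_brute <- function(bases, quals, policy) {
  keep <- quals >= policy$min_base_quality
  bases <- bases[keep]
  depth <- length(bases)
  if (depth < policy$min_coverage) return(NULL)
  tab <- table(bases)
  passing <- character()
  for (al in names(tab)) {
    if (tab[[al]] >= policy$min_reads_per_allele &&
        tab[[al]] / depth >= policy$min_variant_freq)
      passing <- c(passing, al)
  }
  if (length(passing) < 2) return(NULL)
  sort(passing)
}

# Holm step-down decisions written as the literal sorted-loop procedure
holm_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# random read with a controlled mix of good and bad stretches
random_read <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- sample(2:40, len, replace = TRUE)
  list(seq = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
       qual = intToUtf8(q + 33L), q = q)
}

# small deterministic benchmark shared by pipeline-level tests
tiny_benchmark <- function(seed = 11L, n_transcripts = 6L, depth = 25) {
  benchmark_dataset(seed = seed, n_transcripts = n_transcripts, depth = depth)
}

# build a pileup object directly from per-row (contig, pos, pool, base,
# qual, n) specifications, bypassing mapping
make_pileup <- function(..., contig_lengths = c(tigA = 1000L)) {
  dt <- data.table::rbindlist(lapply(list(...), function(r)
    data.table::data.table(contig = r[[1]], pos = as.integer(r[[2]]),
                           pool = r[[3]], base = r[[4]],
                           qual = as.integer(r[[5]]), n = as.integer(r[[6]]))))
  data.table::setkey(dt, contig, pos, pool)
  data.table::setattr(dt, "contig_lengths", contig_lengths)
  data.table::setattr(dt, "pools", sort(unique(dt$pool)))
  data.table::setattr(dt, "class", c("pileup", class(dt)))
  dt
}
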