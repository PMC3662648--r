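# Contig-level filters: per-pool coverage summaries, the high-coverage
# dataset, elevation-unique contigs, and redundancy classification by
# pairwise overlap alignment.

#' Per-contig, per-pool coverage summaries
#'
#' Mean coverage is aligned bases per reference base; ambiguous placements
#' are excluded, matching pileup construction.
#'
#' @param placements placement table
#' @param reference reference sequences
#' @return data.table: contig, length, and per pool mean_cov_<pool>,
#'   n_reads_<pool> (zero where a pool contributed no reads)
#' @export
contig_coverage_summary <- function(placements, reference) {
  ref <- ref_as_character(reference)
  pl <- placements[ambiguous == FALSE]
  base <- data.table(contig = names(ref), length = nchar(ref))
  pools <- sort(unique(placements$pool))
  if (length(pools) == 0) pools <- c("high", "low")
  agg <- pl[, .(bases = sum(span), n_reads = .N), by = .(contig, pool)]
  for (p in pools) {
    a <- agg[pool == p]
    base[, (sprintf("mean_cov_%s", p)) :=
           ifelse(is.na(a$bases[match(contig, a$contig)]), 0,
                  a$bases[match(contig, a$contig)] / length)]
    base[, (sprintf("n_reads_%s", p)) := {
      v <- a$n_reads[match(contig, a$contig)]
      ifelse(is.na(v), 0L, v)
    }]
  }
  setattr(base, "pools", pools)
  base[]
}

#' High-coverage contig filter
#'
#' Retains contigs at least `min_length` bases long whose mean coverage is
#' at least `min_cov` in every pool.
#'
#' @param summaries output of [contig_coverage_summary()]
#' @param min_length minimum contig length (default 200)
#' @param min_cov minimum per-pool mean coverage (default 5)
#' @param strict when TRUE require coverage strictly greater than `min_cov`
#' @return character vector of retained contig ids
#' @export
filter_high_coverage <- function(summaries, min_length = 200L, min_cov = 5,
                                 strict = FALSE) {
  pools <- attr(summaries, "pools") %||%
    sub("^mean_cov_", "", grep("^mean_cov_", names(summaries), value = TRUE))
  keep <- summaries$length >= min_length
  for (p in pools) {
    cv <- summaries[[sprintf("mean_cov_%s", p)]]
    keep <- keep & if (strict) cv > min_cov else cv >= min_cov
  }
  summaries$contig[keep]
}

#' Elevation-unique contigs
#'
#' A contig is unique to pool P when its pool-P mean coverage reaches
#' `min_cov`, the other pool contributed zero reads, and the contig is at
#' least `min_length` bases.
#'
#' @inheritParams filter_high_coverage
#' @return named list of contig-id character vectors, one per pool
#' @export
find_elevation_unique <- function(summaries, min_length = 200L, min_cov = 5) {
  pools <- attr(summaries, "pools") %||%
    sub("^mean_cov_", "", grep("^mean_cov_", names(summaries), value = TRUE))
  out <- list()
  for (p in pools) {
    others <- setdiff(pools, p)
    keep <- summaries$length >= min_length &
      summaries[[sprintf("mean_cov_%s", p)]] >= min_cov
    for (o in others) keep <- keep & summaries[[sprintf("n_reads_%s", o)]] == 0L
    out[[p]] <- summaries$contig[keep]
  }
  out
}

#' Classify contigs by pairwise sequence redundancy
#'
#' Detects partially or totally overlapping contigs: a pair qualifies when
#' a local alignment reaches `min_similarity` identity over at least
#' `min_length_fraction` of the shorter contig. Candidate pairs are
#' pre-screened by shared k-mers, then aligned with
#' [Biostrings::pairwiseAlignment()]. Each contig is classed as `unique`
#' (no partner), `one_partner`, or `multi_partner` (two or more).
#'
#' @param reference named DNAStringSet or named character
#' @param min_similarity identity over the aligned region (default 0.90)
#' @param min_length_fraction fraction of the shorter contig that must be
#'   covered by the alignment (default 0.5)
#' @param k k-mer length for the candidate screen
#' @param min_shared_kmers shared k-mers required to attempt alignment
#' @return data.table: contig, class, n_partners, partners (comma-joined)
#' @export
cluster_redundant_contigs <- function(reference, min_similarity = 0.90,
                                      min_length_fraction = 0.5,
                                      k = 16L, min_shared_kmers = 5L) {
  ref <- ref_as_character(reference)
  if (length(ref) < 1) stopf("need at least one contig")
  ids <- names(ref)
  partners <- stats::setNames(vector("list", length(ref)), ids)
  if (length(ref) > 1) {
    # k-mer candidate screen on both strands
    km <- rbindlist(lapply(ids, function(nm) {
      L <- nchar(ref[[nm]])
      if (L < k) return(NULL)
      st <- seq_len(L - k + 1L)
      data.table(kmer = substring(ref[[nm]], st, st + k - 1L), contig = nm)
    }))
    km <- unique(km)
    kmrc <- copy(km)[, kmer := revcomp(kmer)]
    both <- rbindlist(list(km, kmrc))
    pairs <- merge(km, both, by = "kmer", allow.cartesian = TRUE)[contig.x < contig.y]
    cand <- pairs[, .N, by = .(contig.x, contig.y)][N >= min_shared_kmers]
    if (nrow(cand) > 0) {
      for (r in seq_len(nrow(cand))) {
        a <- cand$contig.x[r]; b <- cand$contig.y[r]
        if (qualifying_overlap(ref[[a]], ref[[b]], min_similarity,
                               min_length_fraction)) {
          partners[[a]] <- c(partners[[a]], b)
          partners[[b]] <- c(partners[[b]], a)
        }
      }
    }
  }
  np <- lengths(partners)
  data.table(contig = ids,
             class = ifelse(np == 0L, "unique",
                            ifelse(np == 1L, "one_partner", "multi_partner")),
             n_partners = np,
             partners = vapply(partners, function(x)
               paste(sort(x), collapse = ","), character(1)))
}

# local alignment overlap check (either strand)
qualifying_overlap <- function(a, b, min_similarity, min_length_fraction) {
  shorter <- min(nchar(a), nchar(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (bb in c(b, revcomp(b))) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(bb),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    if (alen == 0) next
    ident <- Biostrings::nmatch(aln) / alen
    if (ident >= min_similarity && alen >= min_length_fraction * shorter)
      return(TRUE)
  }
  FALSE
}

#' Write a contig summary table as TSV
#' @param summaries output of [contig_coverage_summary()]
#' @param path output TSV
#' @export
write_contig_summary <- function(summaries, path) {
  fwrite(summaries, path, sep = "\t")
  invisible(path)
}
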