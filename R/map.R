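# Ungapped seed-and-extend read mapping against reference contigs, with
# identity and length-fraction acceptance thresholds, SAM import/export,
# and per-pool pileup construction.
#
# Coordinates are 0-based half-open internally (index arithmetic) and
# 1-based in every placement/pileup table the package emits.

#' Mapping policy
#'
#' @param min_similarity minimum identity (matches / aligned span) over the
#'   aligned region; default 0.90
#' @param min_length_fraction minimum aligned span as a fraction of read
#'   length; default 0.5
#' @param seed_length exact-match seed length in bases
#' @return a `mapping_policy` list
#' @export
mapping_policy <- function(min_similarity = 0.90, min_length_fraction = 0.5,
                           seed_length = 15L) {
  if (min_similarity <= 0 || min_similarity > 1) stopf("min_similarity must be in (0,1]")
  if (min_length_fraction <= 0 || min_length_fraction > 1)
    stopf("min_length_fraction must be in (0,1]")
  if (seed_length < 5) stopf("seed_length must be >= 5")
  structure(list(min_similarity = min_similarity,
                 min_length_fraction = min_length_fraction,
                 seed_length = as.integer(seed_length)),
            class = "mapping_policy")
}

#' Build an exact-match k-mer index of the reference
#' @param reference named DNAStringSet or named character vector
#' @param k k-mer length
#' @return keyed data.table (kmer, contig, pos); attribute "ref" holds the
#'   reference as named character, "k" the k-mer length
#' @export
reference_index <- function(reference, k = 15L) {
  ref <- ref_as_character(reference)
  if (length(ref) == 0) stopf("empty reference set")
  idx <- rbindlist(lapply(names(ref), function(nm) {
    L <- nchar(ref[[nm]])
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table(kmer = substring(ref[[nm]], starts, starts + k - 1L),
               contig = nm, pos = starts)
  }))
  setkey(idx, kmer)
  setattr(idx, "ref", ref)
  setattr(idx, "k", as.integer(k))
  idx
}

# mismatches between two equal-length strings
count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Map a set of reads onto reference contigs
#'
#' Seed-and-extend, ungapped: exact k-mer seeds taken at the read start,
#' middle and end propose diagonals on either strand; each candidate is
#' scored by full-read comparison clipped at contig bounds. The
#' best-scoring placement is accepted iff identity >= min_similarity and
#' aligned fraction >= min_length_fraction. Reads with more than one
#' best-scoring placement are flagged ambiguous (excluded from pileups);
#' the reported one is the lowest (contig, position).
#'
#' @param reads a `read_set` (a "pool" column is carried through)
#' @param index a [reference_index()] (or reference sequences, indexed on
#'   the fly with the policy's seed length)
#' @param policy a `mapping_policy`
#' @return data.table of placements: id, pool, contig, start (1-based),
#'   strand, read_len, aln_start (1-based offset in the oriented read),
#'   span, matches, identity, fraction, ambiguous. Unmapped reads are
#'   absent; attribute "n_unmapped" counts them.
#' @export
map_reads <- function(reads, index, policy = mapping_policy()) {
  if (!is.data.table(index) || is.null(attr(index, "ref")))
    index <- reference_index(index, policy$seed_length)
  ref <- attr(index, "ref")
  k <- attr(index, "k")
  n <- nrow(reads)
  if (n == 0) return(empty_placements())
  rl <- nchar(reads$seq)
  if (any(rl < k)) stopf("%d read(s) shorter than the seed length %d", sum(rl < k), k)

  orient <- list(`+` = reads$seq, `-` = revcomp(reads$seq))
  cand_list <- list()
  for (strand in c("+", "-")) {
    sq <- orient[[strand]]
    offs <- cbind(1L, pmax(1L, (rl - k) %/% 2L + 1L), rl - k + 1L)
    for (j in 1:3) {
      o <- offs[, j]
      seeds <- data.table(kmer = substr(sq, o, o + k - 1L),
                          read = seq_len(n), offset = o)
      hit <- index[seeds, on = "kmer", nomatch = NULL,
                   .(read, offset, contig, pos)]
      if (nrow(hit)) {
        hit[, `:=`(strand = strand, start = pos - offset + 1L)]
        cand_list[[length(cand_list) + 1L]] <- hit[, .(read, strand, contig, start)]
      }
    }
  }
  n_unmapped <- 0L
  if (!length(cand_list)) {
    out <- empty_placements()
    setattr(out, "n_unmapped", n)
    return(out)
  }
  cand <- unique(rbindlist(cand_list))

  # verify candidates: ungapped comparison clipped at contig bounds
  clen <- nchar(ref)[cand$contig]
  a_lo <- pmax(1L, cand$start)                     # contig coords
  a_hi <- pmin(clen, cand$start + rl[cand$read] - 1L)
  keepable <- a_hi >= a_lo
  cand <- cand[keepable]
  a_lo <- a_lo[keepable]; a_hi <- a_hi[keepable]
  span <- a_hi - a_lo + 1L
  r_lo <- a_lo - cand$start + 1L                   # oriented-read coords
  refsub <- substr(ref[cand$contig], a_lo, a_hi)
  readsub <- substr(orient[["+"]][cand$read], r_lo, r_lo + span - 1L)
  neg <- cand$strand == "-"
  if (any(neg))
    readsub[neg] <- substr(orient[["-"]][cand$read[neg]], r_lo[neg],
                           r_lo[neg] + span[neg] - 1L)
  mism <- mapply(count_mismatches, readsub, refsub, USE.NAMES = FALSE)
  cand[, `:=`(read_len = rl[read], aln_start = r_lo, span = span,
              matches = span - mism)]
  cand[, `:=`(identity = matches / span, fraction = span / read_len)]
  cand <- cand[identity >= policy$min_similarity &
               fraction >= policy$min_length_fraction]
  if (nrow(cand) == 0) {
    out <- empty_placements()
    setattr(out, "n_unmapped", n)
    return(out)
  }
  setorder(cand, read, -matches, contig, start)
  best <- cand[, {
    top <- matches[1]
    nb <- sum(matches == top)
    .SD[1][, ambiguous := nb > 1L]
  }, by = read]
  out <- data.table(id = reads$id[best$read],
                    pool = if ("pool" %in% names(reads)) reads$pool[best$read] else NA_character_,
                    contig = best$contig, start = pmax(1L, best$start),
                    strand = best$strand, read_len = best$read_len,
                    aln_start = best$aln_start, span = best$span,
                    matches = best$matches, identity = best$identity,
                    fraction = best$fraction, ambiguous = best$ambiguous)
  setattr(out, "n_unmapped", n - nrow(out))
  out
}

empty_placements <- function() {
  data.table(id = character(), pool = character(), contig = character(),
             start = integer(), strand = character(), read_len = integer(),
             aln_start = integer(), span = integer(), matches = integer(),
             identity = numeric(), fraction = numeric(), ambiguous = logical())
}

#' Map a single read
#'
#' @param seq read sequence
#' @param index reference index or reference sequences
#' @param policy a `mapping_policy`
#' @param id read identifier
#' @return a one-row placement data.table, or NULL when unmapped
#' @export
map_read <- function(seq, index, policy = mapping_policy(), id = "read1") {
  qual <- phred_to_string(rep.int(30L, nchar(seq)))
  pl <- map_reads(read_set(id, seq, qual), index, policy)
  if (nrow(pl) == 0) NULL else pl
}

# SAM import/export ---------------------------------------------------------

#' Write placements as SAM
#'
#' Emits one ungapped record per placement (soft clips for read bases
#' outside contig bounds), with NM set to the mismatch count. Ambiguous
#' placements get MAPQ 0, unique ones MAPQ 60. Unplaced reads are omitted.
#'
#' @param placements placement table from [map_reads()]
#' @param reads the `read_set` the placements refer to
#' @param reference reference sequences (for header lengths)
#' @param path output SAM path
#' @export
write_sam <- function(placements, reads, reference, path) {
  ref <- ref_as_character(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)), con)
  if (nrow(placements) == 0) return(invisible(path))
  rs <- reads[match(placements$id, reads$id)]
  seq <- rs$seq; qual <- rs$qual
  neg <- placements$strand == "-"
  seq[neg] <- revcomp(seq[neg])
  qual[neg] <- reverse_string(qual[neg])
  lead <- placements$aln_start - 1L
  trail <- placements$read_len - placements$aln_start - placements$span + 1L
  cigar <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                  placements$span, "M",
                  ifelse(trail > 0, paste0(trail, "S"), ""))
  lines <- paste(placements$id,
                 ifelse(neg, 16L, 0L),
                 placements$contig,
                 placements$start,
                 ifelse(placements$ambiguous, 0L, 60L),
                 cigar, "*", 0L, 0L, seq, qual,
                 paste0("NM:i:", placements$span - placements$matches),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Ingest alignments from a SAM file
#'
#' Accepts mapped, ungapped records (CIGAR limited to M with optional
#' soft/hard clips), recomputes identity from the NM tag (or by per-base
#' comparison against the reference when NM is absent), and applies the
#' same identity / length-fraction acceptance rules as [map_reads()].
#'
#' @param path SAM file
#' @param reference reference sequences the records were aligned to
#' @param policy a `mapping_policy`
#' @param pool_from_name when TRUE (default) the pool label is parsed from
#'   the leading "pool:" field of each read name; otherwise supply `pool`
#' @param pool explicit pool label applied to every record
#' @return list(placements, reads, log) where log counts records skipped as
#'   unmapped, unsupported (gapped), unknown-contig, or rejected by the
#'   thresholds
#' @export
ingest_alignments <- function(path, reference, policy = mapping_policy(),
                              pool_from_name = TRUE, pool = NA_character_) {
  ref <- ref_as_character(reference)
  bam <- Rsamtools::asBam(path, tempfile(fileext = ".bam"),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  log <- c(unmapped = 0L, unsupported = 0L, unknown_contig = 0L, rejected = 0L)
  if (length(b$qname) == 0)
    return(list(placements = empty_placements(),
                reads = read_set(character(), character(), character()),
                log = log))
  rec <- data.table(id = b$qname, flag = b$flag,
                    contig = as.character(b$rname), start = b$pos,
                    cigar = b$cigar,
                    seq = as.character(b$seq), qual = as.character(b$qual),
                    nm = as.integer(b$tag$NM %||% rep(NA_integer_, length(b$qname))))

  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  log["unmapped"] <- sum(unmapped)
  rec <- rec[!unmapped]
  ok_cigar <- grepl("^(\\d+[SH])?\\d+M(\\d+[SH])?$", rec$cigar)
  log["unsupported"] <- sum(!ok_cigar)
  rec <- rec[ok_cigar]
  known <- rec$contig %in% names(ref)
  if (any(!known)) {
    log["unknown_contig"] <- sum(!known)
    stopf("%d SAM record(s) reference contigs absent from the reference set",
          sum(!known))
  }
  if (nrow(rec) == 0)
    return(list(placements = empty_placements(),
                reads = read_set(character(), character(), character()),
                log = log))

  lead <- suppressWarnings(as.integer(sub("^(\\d+)[SH].*$", "\\1", rec$cigar)))
  lead[!grepl("^\\d+[SH]", rec$cigar)] <- 0L
  span <- as.integer(sub("^(?:\\d+[SH])?(\\d+)M.*$", "\\1", rec$cigar))
  rec[, `:=`(aln_start = lead + 1L, span = span, read_len = nchar(seq))]

  # identity: NM tag when present, else direct comparison to the reference
  need <- is.na(rec$nm)
  if (any(need)) {
    refsub <- substr(ref[rec$contig[need]], rec$start[need],
                     rec$start[need] + rec$span[need] - 1L)
    readsub <- substr(rec$seq[need], rec$aln_start[need],
                      rec$aln_start[need] + rec$span[need] - 1L)
    rec$nm[need] <- mapply(count_mismatches, readsub, refsub, USE.NAMES = FALSE)
  }
  rec[, `:=`(matches = span - nm, identity = (span - nm) / span,
             fraction = span / read_len)]
  pass <- rec$identity >= policy$min_similarity &
    rec$fraction >= policy$min_length_fraction
  log["rejected"] <- sum(!pass)
  rec <- rec[pass]
  pool_lab <- if (pool_from_name) sub(":.*$", "", rec$id) else rep(pool, nrow(rec))
  strand <- ifelse(bitwAnd(rec$flag, 16L) != 0L, "-", "+")
  placements <- data.table(id = rec$id, pool = pool_lab, contig = rec$contig,
                           start = rec$start, strand = strand,
                           read_len = rec$read_len, aln_start = rec$aln_start,
                           span = rec$span, matches = rec$matches,
                           identity = rec$identity, fraction = rec$fraction,
                           ambiguous = FALSE)
  # reads table holds forward-oriented sequences as map_reads() would see them
  seqs <- rec$seq; quals <- rec$qual
  neg <- strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  quals[neg] <- reverse_string(quals[neg])
  reads <- read_set(rec$id, seqs, quals, pool = pool_lab)
  list(placements = placements, reads = reads, log = log)
}

# Pileups --------------------------------------------------------------------

#' Build per-pool pileups from placements
#'
#' Expands each accepted (non-ambiguous) placement into per-position base
#' and quality contributions and aggregates them into counts. Aligned
#' mismatches contribute their read base with its quality.
#'
#' @param placements placement table from [map_reads()] / [ingest_alignments()]
#' @param reads the `read_set` the placements refer to (untrimmed-oriented)
#' @param reference reference sequences (bounds checks, contig lengths)
#' @param include_ambiguous include multi-best placements (default FALSE)
#' @return a `pileup`: data.table with one row per (contig, pos, pool,
#'   base, qual) carrying a count `n`; attributes "contig_lengths" and
#'   "pools"
#' @export
build_pileups <- function(placements, reads, reference,
                          include_ambiguous = FALSE) {
  ref <- ref_as_character(reference)
  pl <- placements
  if (!include_ambiguous) pl <- pl[ambiguous == FALSE]
  if (nrow(pl) > 0) {
    if (any(pl$start < 1L) ||
        any(pl$start + pl$span - 1L > nchar(ref)[pl$contig]))
      stopf("placement exceeds contig bounds")
    ix <- match(pl$id, reads$id)
    if (anyNA(ix)) stopf("placements reference unknown reads")
    seq <- reads$seq[ix]; qual <- reads$qual[ix]
    neg <- pl$strand == "-"
    seq[neg] <- revcomp(seq[neg])
    qual[neg] <- reverse_string(qual[neg])
    aseq <- substr(seq, pl$aln_start, pl$aln_start + pl$span - 1L)
    aqual <- substr(qual, pl$aln_start, pl$aln_start + pl$span - 1L)
    n_per <- pl$span
    base <- unlist(strsplit(aseq, "", fixed = TRUE), use.names = FALSE)
    qint <- unlist(lapply(aqual, function(s) utf8ToInt(s)), use.names = FALSE) - 33L
    cols <- data.table(contig = rep(pl$contig, n_per),
                       pos = sequence(n_per) + rep(pl$start - 1L, n_per),
                       pool = rep(pl$pool, n_per),
                       base = base, qual = qint)
    pu <- cols[, .N, by = .(contig, pos, pool, base, qual)]
    setnames(pu, "N", "n")
  } else {
    pu <- data.table(contig = character(), pos = integer(), pool = character(),
                     base = character(), qual = integer(), n = integer())
  }
  setkey(pu, contig, pos, pool)
  setattr(pu, "contig_lengths", nchar(ref))
  setattr(pu, "pools", sort(unique(placements$pool)))
  setattr(pu, "class", c("pileup", class(pu)))
  pu
}

#' Per-column depth of a pileup
#'
#' @param pileup a `pileup`
#' @param min_base_quality count only bases at or above this phred score
#' @return data.table (contig, pos, pool, depth)
#' @export
pileup_depth <- function(pileup, min_base_quality = 0L) {
  pileup[qual >= min_base_quality, .(depth = sum(n)), by = .(contig, pos, pool)]
}
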