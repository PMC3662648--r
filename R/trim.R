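# Quality trimming: exact adapter clipping, fixed terminal trimming, and
# modified-Mott best-segment selection on per-base error probabilities,
# followed by a minimum-length filter.

#' Trimming policy
#'
#' @param quality_limit error-probability threshold for the Mott segment
#'   score (bases with error probability above this count against the
#'   segment); default 0.05
#' @param terminal_trim bases removed unconditionally from each end
#' @param min_length reads shorter than this after trimming are discarded
#' @param adapters optional character vector of literal adapter sequences,
#'   clipped when exactly matching a read prefix or suffix
#' @return a `trim_policy` list
#' @export
trim_policy <- function(quality_limit = 0.05, terminal_trim = 5L,
                        min_length = 100L, adapters = character()) {
  if (quality_limit <= 0 || quality_limit >= 1) stopf("quality_limit must be in (0,1)")
  if (terminal_trim < 0) stopf("terminal_trim must be >= 0")
  if (min_length < 1) stopf("min_length must be >= 1")
  structure(list(quality_limit = quality_limit,
                 terminal_trim = as.integer(terminal_trim),
                 min_length = as.integer(min_length),
                 adapters = toupper(adapters)),
            class = "trim_policy")
}

#' Modified-Mott best segment of a read
#'
#' Scores each base as (limit - p_i), p_i its error probability, and returns
#' the contiguous run maximizing the summed score, as running-sum trimmers
#' do. Empty when the maximum is <= 0. Ties are broken leftmost-first, then
#' longest.
#'
#' @param p numeric vector of per-base error probabilities
#' @param limit error-probability threshold
#' @return integer c(start, end), both 0 when the best segment is empty
#' @export
mott_segment <- function(p, limit) {
  L <- length(p)
  if (L == 0L) return(c(start = 0L, end = 0L))
  s <- limit - p
  P <- c(0, cumsum(s))              # P[a] = sum of first a-1 scores
  pre <- P[seq_len(L)]              # prefixes usable as segment starts
  runmin <- cummin(pre)
  # earliest index attaining each running minimum
  is_new <- pre <= runmin & !duplicated(runmin)
  argmin <- cummax(ifelse(is_new, seq_len(L), 0L))
  val <- P[2:(L + 1)] - runmin      # best sum ending at each position
  best <- max(val)
  if (best <= 1e-12) return(c(start = 0L, end = 0L))
  cand <- which(val >= best - 1e-12)
  starts <- argmin[cand]
  keep <- cand[starts == min(starts)]
  c(start = min(starts), end = max(keep))
}

#' Trim a single read under a policy
#'
#' Operations are applied in a fixed order: exact adapter clipping at the
#' ends, removal of `terminal_trim` bases from each end, modified-Mott
#' quality segment selection, then the minimum-length filter.
#'
#' @param seq read sequence (character scalar)
#' @param qual phred+33 quality string of equal length
#' @param policy a `trim_policy`
#' @return list(seq, qual, kept, start, end): `kept` FALSE when discarded;
#'   start/end give the retained 1-based window of the input read
#' @export
trim_read <- function(seq, qual, policy = trim_policy()) {
  if (nchar(seq) != nchar(qual)) stopf("sequence/quality length mismatch")
  lo <- 1L
  hi <- nchar(seq)
  for (ad in policy$adapters) {
    la <- nchar(ad)
    if (la > 0 && hi - lo + 1L >= la) {
      if (substr(seq, lo, lo + la - 1L) == ad) lo <- lo + la
      if (hi - lo + 1L >= la && substr(seq, hi - la + 1L, hi) == ad) hi <- hi - la
    }
  }
  lo <- lo + policy$terminal_trim
  hi <- hi - policy$terminal_trim
  if (hi >= lo) {
    q <- phred_from_string(substr(qual, lo, hi))
    seg <- mott_segment(phred_to_error(q), policy$quality_limit)
    if (seg[["start"]] == 0L) {
      lo <- 1L; hi <- 0L
    } else {
      hi <- lo + seg[["end"]] - 1L
      lo <- lo + seg[["start"]] - 1L
    }
  }
  len <- max(0L, hi - lo + 1L)
  if (len < policy$min_length) {
    return(list(seq = "", qual = "", kept = FALSE, start = 0L, end = 0L))
  }
  list(seq = substr(seq, lo, hi), qual = substr(qual, lo, hi),
       kept = TRUE, start = lo, end = hi)
}

#' Trim every read in a read set
#'
#' @param reads a `read_set`
#' @param policy a `trim_policy`
#' @return a `read_set` of retained, trimmed reads; attribute
#'   "n_discarded" counts reads dropped by the length filter
#' @export
trim_read_set <- function(reads, policy = trim_policy()) {
  n <- nrow(reads)
  out_seq <- character(n)
  out_qual <- character(n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    tr <- trim_read(reads$seq[i], reads$qual[i], policy)
    kept[i] <- tr$kept
    if (tr$kept) {
      out_seq[i] <- tr$seq
      out_qual[i] <- tr$qual
    }
  }
  res <- read_set(reads$id[kept], out_seq[kept], out_qual[kept],
                  pool = if ("pool" %in% names(reads)) reads$pool[kept] else NULL)
  setattr(res, "n_discarded", sum(!kept))
  res
}

#' Summarize a read set
#'
#' @param reads a `read_set`
#' @return list(n_reads, n_bases, mean_read_length); mean is NA (flagged
#'   undefined) for an empty set
#' @export
summarize_read_set <- function(reads) {
  n <- nrow(reads)
  b <- if (n > 0) sum(nchar(reads$seq)) else 0L
  list(n_reads = n, n_bases = b,
       mean_read_length = if (n > 0) b / n else NA_real_)
}

#' Write read-set summaries for several pools as TSV
#' @param summaries named list of [summarize_read_set()] results
#' @param path output TSV
#' @export
write_read_summary <- function(summaries, path) {
  dt <- rbindlist(lapply(names(summaries), function(nm)
    data.table(pool = nm, n_reads = summaries[[nm]]$n_reads,
               n_bases = summaries[[nm]]$n_bases,
               mean_read_length = summaries[[nm]]$mean_read_length)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
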