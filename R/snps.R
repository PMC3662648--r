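# Per-pool SNP calling under coverage / frequency / reads-per-allele /
# base-quality thresholds, cross-pool merging into the three
# polymorphic/fixed categories, the major-allele divergence index,
# transition/transversion accounting, and candidate-panel selection.

#' SNP calling policy
#'
#' Defaults are the thresholds used throughout: coverage 8x, variant
#' frequency 10%, two reads per allele, base quality 20.
#'
#' @param min_coverage minimum quality-passing depth at a site
#' @param min_variant_freq minimum within-pool allele frequency
#' @param min_reads_per_allele minimum quality-passing reads per allele
#' @param min_base_quality minimum phred quality for a read base to count
#' @return a `calling_policy` list
#' @export
calling_policy <- function(min_coverage = 8L, min_variant_freq = 0.10,
                           min_reads_per_allele = 2L, min_base_quality = 20L) {
  if (min_coverage < 1 || min_reads_per_allele < 1 || min_base_quality < 0)
    stopf("thresholds must be positive")
  if (min_variant_freq <= 0 || min_variant_freq >= 1)
    stopf("min_variant_freq must be in (0,1)")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_variant_freq = min_variant_freq,
                 min_reads_per_allele = as.integer(min_reads_per_allele),
                 min_base_quality = as.integer(min_base_quality)),
            class = "calling_policy")
}

# quality-passing allele counts per column for one pool
pool_allele_counts <- function(pileup, which_pool, policy) {
  pu <- pileup[pool == which_pool & qual >= policy$min_base_quality]
  ac <- pu[, .(count = sum(n)), by = .(contig, pos, base)]
  ac[, depth := sum(count), by = .(contig, pos)]
  ac
}

#' Call SNPs within one pool
#'
#' A column yields a call iff its quality-passing depth reaches
#' `min_coverage` and at least two alleles each have at least
#' `min_reads_per_allele` quality-passing reads and frequency at least
#' `min_variant_freq` of the quality-passing depth. Frequencies are
#' computed over quality-passing reads.
#'
#' @param pileup a `pileup` from [build_pileups()]
#' @param which_pool pool label to call (e.g. "high")
#' @param policy a `calling_policy`
#' @return data.table (long form): contig, pos, allele, count, freq, depth
#'   for every passing allele at every called site; attribute "n_columns"
#'   gives the number of columns examined, "n_no_call" those tallied as
#'   non-calls
#' @export
call_group_snps <- function(pileup, which_pool, policy = calling_policy()) {
  ac <- pool_allele_counts(pileup, which_pool, policy)
  n_columns <- if (nrow(ac)) nrow(unique(ac[, .(contig, pos)])) else 0L
  ac <- ac[depth >= policy$min_coverage]
  ac[, freq := count / depth]
  ac[, pass := count >= policy$min_reads_per_allele & freq >= policy$min_variant_freq]
  ac[, n_pass := sum(pass), by = .(contig, pos)]
  calls <- ac[n_pass >= 2L & pass == TRUE,
              .(contig, pos, allele = base, count, freq, depth)]
  setorder(calls, contig, pos, -count, allele)
  setattr(calls, "n_columns", n_columns)
  setattr(calls, "n_no_call", n_columns - nrow(unique(calls[, .(contig, pos)])))
  calls[]
}

#' Merge per-pool SNP calls and classify each site across pools
#'
#' Categories: `a` (polymorphic in both pools), `b` (polymorphic in one,
#' fixed in the other), `c` (fixed for different alleles). A pool counts as
#' fixed only when its quality-passing depth reaches `min_coverage` and a
#' single allele passes the quality filter; a site polymorphic in one pool
#' whose other pool fails that bar is `undetermined` and excluded from the
#' category counts. Category-c sites are screened from the pileup columns
#' where both pools are fixed, with different alleles.
#'
#' Divergence D and the substitution class are filled for determined
#' biallelic sites (see [divergence_index()]); sites with more than two
#' relevant alleles are retained with class "multiallelic" and D = NA.
#'
#' @param calls_high,calls_low per-pool call tables from [call_group_snps()]
#' @param pileup the `pileup` both call tables derive from
#' @param policy the `calling_policy` used for calling
#' @param pools character(2): labels of the (first, second) pool as used in
#'   the pileup; the first is reported as "high"
#' @return data.table: contig, pos, category (a/b/c/undetermined), alleles
#'   (comma-joined), per-pool frequency of the combined-pool major allele
#'   (freq_high/freq_low), depths, major allele, divergence, subst_class
#' @export
merge_and_classify <- function(calls_high, calls_low, pileup,
                               policy = calling_policy(),
                               pools = c("high", "low")) {
  ach <- pool_allele_counts(pileup, pools[1], policy)
  acl <- pool_allele_counts(pileup, pools[2], policy)

  key_of <- function(dt) if (nrow(dt)) unique(dt[, .(contig, pos)]) else
    data.table(contig = character(), pos = integer())
  ch <- key_of(calls_high)
  cl <- key_of(calls_low)
  ch[, poly_high := TRUE]
  cl[, poly_low := TRUE]

  # per-column fixation status (depth ok + single quality-passing allele)
  fix_stat <- function(ac) {
    st <- ac[, .(depth = depth[1], n_alleles = .N,
                 top_allele = base[which.max(count)]), by = .(contig, pos)]
    st[, fixed := depth >= policy$min_coverage & n_alleles == 1L]
    st
  }
  sh <- fix_stat(ach)
  sl <- fix_stat(acl)

  # site universe: called in either pool, plus fixed-different columns
  sites <- merge(ch, cl, by = c("contig", "pos"), all = TRUE)
  cc <- merge(sh[fixed == TRUE], sl[fixed == TRUE], by = c("contig", "pos"),
              suffixes = c("_h", "_l"))
  cc <- cc[top_allele_h != top_allele_l, .(contig, pos)]
  if (nrow(cc)) {
    cc[, `:=`(poly_high = NA, poly_low = NA)]
    sites <- merge(sites, cc[, .(contig, pos, is_c = TRUE)],
                   by = c("contig", "pos"), all = TRUE)
  } else {
    sites[, is_c := FALSE]
  }
  for (col in c("poly_high", "poly_low", "is_c"))
    sites[is.na(get(col)), (col) := FALSE]

  sites <- merge(sites, sh[, .(contig, pos, depth_high = depth,
                               fixed_high = fixed)],
                 by = c("contig", "pos"), all.x = TRUE)
  sites <- merge(sites, sl[, .(contig, pos, depth_low = depth,
                               fixed_low = fixed)],
                 by = c("contig", "pos"), all.x = TRUE)
  sites[is.na(depth_high), depth_high := 0L]
  sites[is.na(depth_low), depth_low := 0L]
  sites[is.na(fixed_high), fixed_high := FALSE]
  sites[is.na(fixed_low), fixed_low := FALSE]

  sites[, category := "undetermined"]
  sites[poly_high & poly_low, category := "a"]
  sites[poly_high & !poly_low & fixed_low, category := "b"]
  sites[poly_low & !poly_high & fixed_high, category := "b"]
  sites[!poly_high & !poly_low & is_c, category := "c"]

  # relevant alleles per site: called passing alleles per pool, or the
  # fixed pool's single allele
  rel <- rbindlist(list(
    if (nrow(calls_high)) calls_high[, .(contig, pos, allele)] else NULL,
    if (nrow(calls_low)) calls_low[, .(contig, pos, allele)] else NULL,
    sh[fixed == TRUE, .(contig, pos, allele = top_allele)],
    sl[fixed == TRUE, .(contig, pos, allele = top_allele)]))
  rel <- unique(rel)[sites[, .(contig, pos)], on = c("contig", "pos"), nomatch = NULL]

  # counts of the relevant alleles in each pool
  cnt_h <- ach[rel, on = c("contig", "pos", base = "allele"), nomatch = NA,
               .(contig, pos, allele = base, count_high = count)]
  cnt_l <- acl[rel, on = c("contig", "pos", base = "allele"), nomatch = NA,
               .(contig, pos, allele = base, count_low = count)]
  alleles <- merge(cnt_h, cnt_l, by = c("contig", "pos", "allele"), all = TRUE)
  alleles[is.na(count_high), count_high := 0L]
  alleles[is.na(count_low), count_low := 0L]
  alleles[, combined := count_high + count_low]

  per_site <- alleles[, {
    o <- order(-combined, allele)
    list(alleles = paste(allele[o], collapse = ","),
         n_alleles = .N,
         major = allele[o][1],
         major_count_high = count_high[o][1],
         major_count_low = count_low[o][1])
  }, by = .(contig, pos)]

  out <- merge(sites, per_site, by = c("contig", "pos"), all.x = TRUE)
  out[, freq_high := ifelse(depth_high > 0, major_count_high / depth_high, NA_real_)]
  out[, freq_low := ifelse(depth_low > 0, major_count_low / depth_low, NA_real_)]
  out[, divergence := ifelse(category != "undetermined" & n_alleles == 2L,
                             abs(freq_high - freq_low), NA_real_)]
  out[, subst_class := classify_substitution(alleles, n_alleles)]
  out[category == "undetermined", `:=`(divergence = NA_real_,
                                       subst_class = NA_character_)]
  setorder(out, contig, pos)
  out[, .(contig, pos, category, alleles, n_alleles, major,
          depth_high, depth_low, freq_high, freq_low, divergence, subst_class)]
}

# per-site substitution class from a comma-joined allele string
classify_substitution <- function(alleles, n_alleles) {
  cls <- rep(NA_character_, length(alleles))
  bi <- !is.na(n_alleles) & n_alleles == 2L
  if (any(bi)) {
    pair <- vapply(strsplit(alleles[bi], ",", fixed = TRUE),
                   function(x) paste(sort(x), collapse = "/"), character(1))
    cls[bi] <- ifelse(pair %in% c("A/G", "C/T"), "transition", "transversion")
  }
  cls[!is.na(n_alleles) & n_alleles > 2L] <- "multiallelic"
  cls
}

#' Major-allele divergence index
#'
#' D = |f_high(major) - f_low(major)| where the major allele is the most
#' frequent allele in the combined (both-pool) quality-passing counts, ties
#' broken lexicographically. Frequencies are per-pool counts over
#' quality-passing depth.
#'
#' @param count_high,count_low named integer vectors of per-allele
#'   quality-passing read counts in each pool (names are alleles)
#' @return D in \[0,1\]
#' @export
divergence_index <- function(count_high, count_low) {
  alleles <- union(names(count_high), names(count_low))
  if (length(alleles) < 1) stopf("no alleles supplied")
  ch <- stats::setNames(rep(0L, length(alleles)), alleles)
  cl <- ch
  ch[names(count_high)] <- count_high
  cl[names(count_low)] <- count_low
  if (length(alleles) > 2) stopf("divergence index is defined for biallelic sites")
  dh <- sum(ch); dl <- sum(cl)
  if (dh == 0 || dl == 0) stopf("divergence requires coverage in both pools")
  combined <- ch + cl
  major <- alleles[order(-combined, alleles)][1]
  abs(ch[[major]] / dh - cl[[major]] / dl)
}

#' Transition/transversion classification and aggregate ratio
#'
#' A<->G and C<->T are transitions; every other biallelic pair is a
#' transversion. Multiallelic sites are excluded.
#'
#' @param records merged SNP table from [merge_and_classify()]
#' @return list(n_transitions, n_transversions, ratio); ratio is NA
#'   (flagged undefined) when there are no transversions
#' @export
transition_transversion <- function(records) {
  ts <- sum(records$subst_class == "transition", na.rm = TRUE)
  tv <- sum(records$subst_class == "transversion", na.rm = TRUE)
  list(n_transitions = ts, n_transversions = tv,
       ratio = if (tv > 0) ts / tv else NA_real_)
}

#' Select a candidate panel of strongly diverged, isolated SNPs
#'
#' A site is selected when its divergence reaches `divergence_threshold`,
#' an amplicon window of `amplicon_length` bases centered on it fits within
#' the contig, and no other merged SNP falls inside the window.
#'
#' @param records merged SNP table (determined, biallelic sites considered)
#' @param contig_lengths named integer vector of contig lengths
#' @param divergence_threshold minimum D (default 0.5)
#' @param amplicon_length window size in bases (default 200)
#' @return subset of `records` with window_start / window_end columns
#' @export
select_candidate_panel <- function(records, contig_lengths,
                                   divergence_threshold = 0.5,
                                   amplicon_length = 200L) {
  half <- amplicon_length %/% 2L
  rec <- copy(records)
  rec[, window_start := pos - half]
  rec[, window_end := window_start + amplicon_length - 1L]
  cl <- contig_lengths[rec$contig]
  cand <- rec[!is.na(divergence) & divergence >= divergence_threshold &
              window_start >= 1L & window_end <= cl]
  if (nrow(cand) == 0) return(cand)
  # neighbor exclusion against every merged site (any category)
  all_pos <- records[, .(contig, pos)]
  setkey(all_pos, contig, pos)
  n_in_window <- vapply(seq_len(nrow(cand)), function(i) {
    all_pos[contig == cand$contig[i] & pos >= cand$window_start[i] &
            pos <= cand$window_end[i], .N]
  }, integer(1))
  cand[n_in_window == 1L]
}

#' Write a merged SNP table as TSV (1-based positions)
#' @param records merged SNP table
#' @param path output TSV
#' @export
write_snp_table <- function(records, path) {
  fwrite(records, path, sep = "\t")
  invisible(path)
}
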