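# Synonymous / non-synonymous classification of substitutions between
# aligned haplotypes of a coding region, under the standard or vertebrate
# mitochondrial genetic code.

genetic_code_table <- function(code = c("vertebrate_mitochondrial", "standard")) {
  code <- match.arg(code)
  Biostrings::getGeneticCode(switch(code, standard = "1",
                                    vertebrate_mitochondrial = "2"))
}

#' Translate a coding region
#'
#' The sequence is read from `frame` (0, 1 or 2 bases skipped); the
#' effective length must be a multiple of three. Codons containing N
#' translate to X unless the ambiguity still resolves to a single amino
#' acid. Internal stop codons trigger a warning, as they usually indicate a
#' mis-specified frame.
#'
#' @param seq nucleotide sequence over A/C/G/T/N
#' @param frame reading-frame offset in c(0, 1, 2)
#' @param code "vertebrate_mitochondrial" (default; ATA=Met, TGA=Trp,
#'   AGA/AGG=Stop) or "standard"
#' @return amino-acid string (single-letter, "*" for stop)
#' @export
translate_cds <- function(seq, frame = 0L,
                          code = c("vertebrate_mitochondrial", "standard")) {
  code <- match.arg(code)
  if (!frame %in% 0:2) stopf("frame must be 0, 1 or 2")
  eff <- substr(toupper(seq), frame + 1L, nchar(seq))
  if (nchar(eff) %% 3L != 0L)
    stopf("effective length %d is not a multiple of 3", nchar(eff))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(eff),
                          genetic.code = genetic_code_table(code),
                          if.fuzzy.codon = "solve")))
  if (grepl("\\*", substr(aa, 1L, max(0L, nchar(aa) - 1L))))
    warning("internal stop codon in declared frame", call. = FALSE)
  aa
}

#' Classify nucleotide substitutions between two aligned haplotypes
#'
#' Compares two equal-length, same-frame haplotypes site by site. Each
#' mismatching nucleotide yields one record; codons carrying several
#' differences are evaluated as a whole-codon amino-acid comparison, every
#' site in the codon inheriting the codon's class. Stop-gain substitutions
#' are flagged and counted as non-synonymous.
#'
#' @param hap_a,hap_b aligned nucleotide sequences of equal length
#' @param frame shared reading-frame offset in c(0, 1, 2)
#' @param code genetic code id (see [translate_cds()])
#' @return data.table: pos (1-based nucleotide), codon_index, codon_a,
#'   codon_b, aa_a, aa_b, class ("synonymous"/"nonsynonymous"), stop_gain,
#'   tstv ("transition"/"transversion"); attributes "n_sites" and
#'   "n_nonsynonymous"
#' @export
classify_codon_substitutions <- function(hap_a, hap_b, frame = 0L,
                                         code = c("vertebrate_mitochondrial",
                                                  "standard")) {
  code <- match.arg(code)
  hap_a <- toupper(hap_a); hap_b <- toupper(hap_b)
  if (nchar(hap_a) != nchar(hap_b)) stopf("haplotype length mismatch")
  if (!frame %in% 0:2) stopf("frame must be 0, 1 or 2")
  a <- strsplit(hap_a, "", fixed = TRUE)[[1]]
  b <- strsplit(hap_b, "", fixed = TRUE)[[1]]
  diff_pos <- which(a != b)
  empty <- data.table(pos = integer(), codon_index = integer(),
                      codon_a = character(), codon_b = character(),
                      aa_a = character(), aa_b = character(),
                      class = character(), stop_gain = logical(),
                      tstv = character())
  if (length(diff_pos) == 0) {
    setattr(empty, "n_sites", 0L); setattr(empty, "n_nonsynonymous", 0L)
    return(empty)
  }
  in_frame <- diff_pos > frame &
    diff_pos <= frame + 3L * ((nchar(hap_a) - frame) %/% 3L)
  if (any(!in_frame))
    warning(sprintf("%d substitution(s) outside complete codons skipped",
                    sum(!in_frame)), call. = FALSE)
  diff_pos <- diff_pos[in_frame]
  gc_tab <- genetic_code_table(code)
  codon_of <- function(x, ci) paste(x[(frame + 3L * (ci - 1L) + 1L):
                                      (frame + 3L * ci)], collapse = "")
  ci <- (diff_pos - frame - 1L) %/% 3L + 1L
  recs <- lapply(seq_along(diff_pos), function(i) {
    idx <- ci[i]
    ca <- codon_of(a, idx); cb <- codon_of(b, idx)
    aa_a <- if (grepl("N", ca)) "X" else unname(gc_tab[[ca]])
    aa_b <- if (grepl("N", cb)) "X" else unname(gc_tab[[cb]])
    pair <- paste(sort(c(a[diff_pos[i]], b[diff_pos[i]])), collapse = "/")
    data.table(pos = diff_pos[i], codon_index = idx, codon_a = ca,
               codon_b = cb, aa_a = aa_a, aa_b = aa_b,
               class = if (identical(aa_a, aa_b)) "synonymous" else "nonsynonymous",
               stop_gain = xor(aa_a == "*", aa_b == "*"),
               tstv = if (pair %in% c("A/G", "C/T")) "transition" else "transversion")
  })
  out <- rbindlist(recs)
  setorder(out, pos)
  setattr(out, "n_sites", nrow(out))
  setattr(out, "n_nonsynonymous", sum(out$class == "nonsynonymous"))
  out[]
}
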