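#' @importFrom data.table data.table setkey setkeyv := .N .SD rbindlist setorder fwrite fread as.data.table copy setnames is.data.table setattr tstrsplit
#' @importFrom stats rbinom rnorm runif rpois p.adjust setNames
#' @importFrom utils head tail
NULL

# phred+33 encoding helpers -------------------------------------------------

#' Convert a phred+33 quality string to integer qualities
#' @param qual character scalar (one read's quality string)
#' @return integer vector of phred scores
#' @keywords internal
phred_from_string <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Convert integer phred scores to a phred+33 string
#' @param q integer vector of phred scores (0-41)
#' @keywords internal
phred_to_string <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' Per-base error probability from phred scores
#' @param q integer phred vector
#' @keywords internal
phred_to_error <- function(q) {
  10^(-q / 10)
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stream-specific seed from a base seed
#'
#' Used so that independent stages (genotypes, reads per pool, panel) draw
#' from distinct but reproducible streams. Kept below 2^31 - 1.
#' @keywords internal
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
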