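# Read-set container and FASTA/FASTQ input-output.
#
# A read set is a data.table with columns:
#   id   - read identifier (character, unique)
#   seq  - nucleotide sequence (character, A/C/G/T/N)
#   qual - phred+33 quality string, nchar(qual) == nchar(seq)
# plus an optional "pool" column carrying the population-pool label.

#' Construct a read set
#'
#' @param id character vector of read identifiers
#' @param seq character vector of sequences
#' @param qual character vector of phred+33 quality strings
#' @param pool optional pool labels (e.g. "high"/"low"), recycled
#' @return a `read_set`: a data.table with columns id, seq, qual (and pool)
#' @export
read_set <- function(id, seq, qual, pool = NULL) {
  if (length(id) != length(seq) || length(seq) != length(qual))
    stopf("id, seq and qual must have equal length")
  bad <- nchar(seq) != nchar(qual)
  if (any(bad))
    stopf("sequence/quality length mismatch for %d read(s), first: %s",
          sum(bad), id[which(bad)[1]])
  rs <- data.table(id = as.character(id), seq = toupper(seq), qual = qual)
  if (!is.null(pool)) rs[, pool := rep_len(pool, .N)]
  setattr(rs, "class", c("read_set", class(rs)))
  rs[]
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (phred+33)
#' @param pool optional pool label to attach to every read
#' @return a `read_set`
#' @export
read_fastq <- function(path, pool = NULL) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  read_set(names(x), as.character(x), as.character(q), pool = pool)
}

#' Write a read set to FASTQ (phred+33)
#'
#' @param reads a `read_set`
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read reference contigs from FASTA
#' @param path FASTA file
#' @return named DNAStringSet
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  # keep the first whitespace-delimited token as the contig id, as mappers do
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reference contigs to FASTA
#' @param reference named DNAStringSet (or named character vector)
#' @param path output path
#' @export
write_reference <- function(reference, path) {
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

# internal: reference as a named character vector
ref_as_character <- function(reference) {
  if (is.character(reference)) {
    if (is.null(names(reference))) stopf("reference sequences must be named")
    return(toupper(reference))
  }
  stats::setNames(as.character(reference), names(reference))
}

#' @importFrom data.table setattr
NULL
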