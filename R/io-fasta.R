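#' Read a FASTA file into a validated sequence set
#'
#' Sequences are uppercased on read; only the nucleotide alphabet
#' \code{A, C, G, T, N} is accepted. Duplicate record names and empty records
#' are errors.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return A [Biostrings::DNAStringSet] of uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "acgt"), fa)
#' as.character(readFasta(fa))
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty record(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    off <- regmatches(chr[bad][1L], regexpr("[^ACGTN]", chr[bad][1L]))
    stop("illegal character '", off, "' in sequence ", names(seqs)[bad][1L])
  }
  Biostrings::DNAStringSet(chr)
}

#' Write a sequence set as FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Named lengths of a sequence set
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @return named integer vector of sequence lengths.
#' @export
seqLengths <- function(seqs) {
  setNames(Biostrings::width(seqs), names(seqs))
}
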