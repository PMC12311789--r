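## Plain-text readers/writers for the formats the pipeline exchanges:
## FASTA and FASTQ through Biostrings, tab-separated tables, and JSON
## summaries.

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path input file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads with qualities to FASTQ (Phred+33)
#' @param reads data frame with columns \code{id} (or \code{umi}),
#'   \code{seq}, \code{qual}.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$id %||% reads$umi
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path input file.
#' @return Data frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a tab-separated table
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#' @param path input file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
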