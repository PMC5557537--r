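# Sequence file plumbing. Genomes are held as named character vectors so
# that position arithmetic and substring extraction stay vectorised; FASTA
# parsing and reverse complementation go through Biostrings.

#' Read a FASTA file into a named character vector
#'
#' Contig names containing `"!"` are rejected because `"!"` delimits the
#' encoded read-origin names (see [encode_origin()]).
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector, one element per contig, upper-cased.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("!", names(seqs), fixed = TRUE))) {
    stop("contig names must not contain '!': ",
      paste(grep("!", names(seqs), fixed = TRUE, value = TRUE), collapse = ", "),
      call. = FALSE
    )
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#' @param x Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a 4-line-per-record FASTQ file
#' @param path Path to an uncompressed FASTQ file.
#' @return Data frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", path, call. = FALSE)
  }
  i <- seq(1L, length(lines), by = 4L)
  data.frame(
    name = sub("^@", "", sub("\\s.*$", "", lines[i])),
    seq = lines[i + 1L],
    qual = lines[i + 3L],
    stringsAsFactors = FALSE
  )
}

#' Write reads as FASTQ
#' @param reads Data frame with columns `name`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  out <- character(4L * nrow(reads))
  i <- seq(1L, length(out), by = 4L)
  out[i] <- paste0("@", reads$name)
  out[i + 1L] <- reads$seq
  out[i + 2L] <- "+"
  out[i + 3L] <- reads$qual
  writeLines(out, path)
  invisible(path)
}
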