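#' Read and write sequence files as tibbles
#'
#' Thin tidy wrappers around Biostrings. Sequences are returned in the
#' internal RNA alphabet (T transliterated to U); on disk they are written as
#' DNA, matching what sequencers emit.
#'
#' @param path file path.
#' @return `read_seq_fasta()` and `read_seq_fastq()` return a tibble with
#'   columns `id` and `sequence`.
#' @export
read_seq_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = names(x), sequence = as_rna(as.character(x)))
}

#' @rdname read_seq_fasta
#' @param x tibble with columns `id` and `sequence`.
#' @export
write_seq_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(as_dna(x$sequence))
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' @rdname read_seq_fasta
#' @export
read_seq_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = names(x), sequence = as_rna(as.character(x)))
}

#' @rdname read_seq_fasta
#' @param quality_char single Sanger quality character applied to every base
#'   (default "I", Q40); synthetic reads carry a constant quality.
#' @export
write_seq_fastq <- function(x, path, quality_char = "I") {
  set <- Biostrings::DNAStringSet(as_dna(x$sequence))
  names(set) <- x$id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(x$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
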