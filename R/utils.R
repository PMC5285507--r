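## Internal helpers shared across modules.

#' Coerce a sequence input to a plain uppercase character vector
#'
#' Accepts a character vector, a `Biostrings::DNAStringSet` or a single
#' `DNAString`; names are preserved where present.
#' @noRd
as_dna_character <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString") ||
      inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    stop("sequences must be a character vector or a Biostrings object")
  }
  toupper(x)
}

#' Reverse-complement (DNA alphabet, N preserved)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  x <- as_dna_character(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' Base qualities are not retained: tag identity throughout the pipeline is
#' by sequence alone.
#'
#' @param path path to a FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write reads as Phred+33 FASTQ
#'
#' @param x named character vector of read sequences.
#' @param path output path.
#' @param quality_char single character used for every base quality.
#' @export
write_fastq <- function(x, path, quality_char = "I") {
  x <- as_dna_character(x)
  if (is.null(names(x))) names(x) <- sprintf("read_%06d", seq_along(x))
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              format = "fastq", qualities = q)
  invisible(path)
}

## 0-based T-gap decomposition: lengths of the T runs between consecutive
## non-T characters, including the leading and trailing run.
t_gap_lengths <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  backbone_pos <- which(chars != "T")
  n <- length(chars)
  if (length(backbone_pos) == 0L) return(n)
  c(backbone_pos[1] - 1L,
    diff(backbone_pos) - 1L,
    n - backbone_pos[length(backbone_pos)])
}

strip_t <- function(seq) gsub("T", "", seq, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
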