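#' @useDynLib mirseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Sequences are held internally in the DNA alphabet (T); RNA (U) is accepted
# on input and emitted where mature miRNAs are reported, matching miRBase
# convention.

#' Normalise a sequence to the DNA alphabet
#'
#' Uppercases and replaces U with T. Used on every external sequence input so
#' the pipeline compares sequences in a single alphabet.
#'
#' @param x character vector of nucleotide sequences (DNA or RNA).
#' @return character vector in the DNA alphabet.
#' @export
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Convert a DNA-alphabet sequence to RNA
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA-alphabet sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

# Split a sequence into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Random DNA string(s) of given lengths (vectorised over n).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  vapply(n, function(k) {
    paste(sample(alphabet, k, replace = TRUE), collapse = "")
  }, character(1))
}

# Validate a nucleotide string (DNA or RNA letters only).
check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTUacgtu]", x)
  if (any(bad)) {
    stop(what, " contains characters outside the ACGTU alphabet", call. = FALSE)
  }
  invisible(x)
}

# stopifnot-style scalar checks used across modules
assert_scalar_count <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(name, " must be a single non-negative integer", call. = FALSE)
  }
  invisible(as.integer(x))
}
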