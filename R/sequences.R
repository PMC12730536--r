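#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input and replaces every `T` with `U`, reconciling
#' DNA-alphabet inputs (RefSeq-style) with RNA-alphabet inputs
#' (miRBase-style). Length is preserved and the operation is idempotent.
#'
#' @param raw A single non-empty character string over
#'   `{A,C,G,T,U,a,c,g,t,u}`.
#' @return The normalized RNA string (uppercase, alphabet `{A,C,G,U}`).
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("'raw' must be a single non-empty character string")
  }
  up <- chartr("T", "U", toupper(raw))
  bad <- regexpr("[^ACGU]", up)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(raw, bad, bad), as.integer(bad)))
  }
  up
}

# vectorized form used by the readers
normalize_sequences <- function(raws) {
  vapply(raws, normalize_sequence, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick complement (A<->U, C<->G), reversed. An involution:
#' `reverse_complement(reverse_complement(x))` equals `x`.
#'
#' @param x Character vector of RNA strings (alphabet `{A,C,G,U}`);
#'   empty strings are allowed and map to themselves.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::RNAStringSet(x[nz]))
    )
  }
  out
}

#' Seed region of a mature miRNA (nucleotides 2-7)
#'
#' The seed is the six-nucleotide stretch at positions 2-7 from the 5' end
#' of the mature miRNA, the core determinant of target-binding specificity.
#'
#' @param sequence Mature miRNA RNA string, length >= 7.
#' @return The 6-nt seed string.
#' @export
seed_region <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(nchar(sequence) < 7L)) {
    stop("miRNA sequence shorter than 7 nt has no seed region")
  }
  substr(sequence, 2L, 7L)
}

#' Extended seed of a mature miRNA (nucleotides 2-13)
#'
#' The 12-nt span whose exact antisense occurrence in a transcript anchors
#' a candidate target site.
#'
#' @param sequence Mature miRNA RNA string, length >= 13.
#' @return The 12-nt extended-seed string.
#' @export
extended_seed <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(nchar(sequence) < 13L)) {
    stop("miRNA sequence shorter than 13 nt has no extended seed")
  }
  substr(sequence, 2L, 13L)
}
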