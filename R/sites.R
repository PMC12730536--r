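#' Find candidate target sites by exact antisense matching of miRNA nt 2-13
#'
#' For each miRNA the search pattern is the reverse complement of its
#' extended seed (nucleotides 2-13); every exact occurrence of that 12-mer
#' in a transcript -- including overlapping occurrences -- is reported as a
#' candidate site. Only antisense matches can hybridize, so sense-strand
#' identity is never a site. This is the native equivalent of a short-word
#' alignment at 100% identity and full query coverage, without an external
#' aligner.
#'
#' @param mirnas Data frame with columns `mirna_id` and `sequence`
#'   (all sequences must be >= 13 nt).
#' @param transcripts Data frame with columns `transcript_id` and
#'   `sequence`.
#' @return A data frame of seed matches with columns `mirna_id`,
#'   `transcript_id`, `site_start`, `site_end` (0-based, half-open) and
#'   `site_sequence` (the matched 12-mer), ordered by
#'   `(transcript_id, site_start, mirna_id)`.
#' @export
find_sites <- function(mirnas, transcripts) {
  stopifnot(all(c("mirna_id", "sequence") %in% names(mirnas)),
            all(c("transcript_id", "sequence") %in% names(transcripts)))
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      site_sequence = character(0), stringsAsFactors = FALSE)
  if (nrow(mirnas) == 0L || nrow(transcripts) == 0L) return(empty)
  if (any(nchar(mirnas$sequence) < 13L)) {
    stop("all miRNAs must be >= 13 nt to define an extended seed")
  }
  subjects <- Biostrings::RNAStringSet(transcripts$sequence)
  hits <- vector("list", nrow(mirnas))
  for (k in seq_len(nrow(mirnas))) {
    pattern <- reverse_complement(extended_seed(mirnas$sequence[k]))
    midx <- Biostrings::vmatchPattern(Biostrings::RNAString(pattern), subjects)
    starts <- lapply(seq_along(midx), function(i) BiocGenerics::start(midx[[i]]))
    n_hits <- lengths(starts)
    if (sum(n_hits) == 0L) next
    hits[[k]] <- data.frame(
      mirna_id = mirnas$mirna_id[k],
      transcript_id = rep(transcripts$transcript_id, n_hits),
      site_start = unlist(starts) - 1L,   # to 0-based
      site_sequence = pattern,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out$site_end <- out$site_start + 12L
  out <- out[order(out$transcript_id, out$site_start, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("mirna_id", "transcript_id", "site_start", "site_end", "site_sequence")]
}
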