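REGION_LEVELS <- c("FIVE_UTR", "CDS", "THREE_UTR", "NCRNA")

#' Classify a transcript position into a transcript region
#'
#' Classification is by the seed-match start position, 0-based: noncoding
#' transcripts are `NCRNA`; for coding transcripts the position falls in
#' `FIVE_UTR` when before `cds_start`, in `CDS` when inside the half-open
#' CDS span, and in `THREE_UTR` otherwise. Sites straddling a boundary
#' take the region of their start.
#'
#' @param transcript One-row data frame (or list) with `biotype`,
#'   `sequence`, `cds_start`, `cds_end`.
#' @param site_start 0-based position within the transcript.
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"NCRNA"`.
#' @export
classify_region <- function(transcript, site_start) {
  len <- nchar(transcript$sequence)
  if (site_start < 0L || site_start >= len) {
    stop(sprintf("site_start %d outside transcript of length %d", site_start, len))
  }
  if (transcript$biotype == "noncoding") return("NCRNA")
  if (site_start < transcript$cds_start) return("FIVE_UTR")
  if (site_start < transcript$cds_end) return("CDS")
  "THREE_UTR"
}

#' Attach gene symbols and region labels to accepted sites
#'
#' @param sites Data frame with `mirna_id`, `transcript_id`, `site_start`
#'   and `mfe` columns (accepted duplex energies).
#' @param transcripts Transcriptome data frame from
#'   [read_transcriptome()].
#' @return An interaction data frame with columns `mirna_id`,
#'   `transcript_id`, `gene_symbol`, `region`, `site_start`, `mfe`.
#' @export
annotate_interactions <- function(sites, transcripts) {
  if (nrow(sites) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      gene_symbol = character(0), region = character(0),
                      site_start = integer(0), mfe = numeric(0),
                      stringsAsFactors = FALSE))
  }
  idx <- match(sites$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    stop("unknown transcript_id: ",
         paste(unique(sites$transcript_id[is.na(idx)]), collapse = ", "))
  }
  region <- vapply(seq_len(nrow(sites)), function(r) {
    classify_region(transcripts[idx[r], ], sites$site_start[r])
  }, character(1))
  out <- data.frame(mirna_id = sites$mirna_id,
                    transcript_id = sites$transcript_id,
                    gene_symbol = transcripts$gene_symbol[idx],
                    region = region,
                    site_start = sites$site_start,
                    mfe = sites$mfe,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# histogram bin index for an MFE value: bin k covers the 5-kcal/mol
# interval written [-25-5k, -30-5k) -- left-closed toward more negative
# values, so -30.0 falls in [-30,-35). Bins extend upward (k < 0) when the
# energy threshold is disabled.
.mfe_bin <- function(mfe) as.integer(floor((-25 - mfe) / 5))

.mfe_bin_label <- function(k) sprintf("[%g,%g)", -25 - 5 * k, -30 - 5 * k)

#' Region counts and MFE histogram for an interaction set
#'
#' @param interactions Interaction data frame (see
#'   [annotate_interactions()]).
#' @param bin_width Histogram bin width in kcal/mol (default 5).
#' @return A list with `region_counts` (named integer vector over all
#'   four regions; sums to `nrow(interactions)`) and `mfe_histogram`
#'   (data frame: `bin`, one count column per region, `total`).
#' @export
summarize_interactions <- function(interactions, bin_width = 5) {
  region_counts <- vapply(REGION_LEVELS, function(rg) {
    sum(interactions$region == rg)
  }, integer(1))
  if (nrow(interactions) == 0L) {
    hist_df <- data.frame(bin = character(0))
    for (rg in REGION_LEVELS) hist_df[[rg]] <- integer(0)
    hist_df$total <- integer(0)
    return(list(region_counts = region_counts, mfe_histogram = hist_df))
  }
  ks <- .mfe_bin(interactions$mfe)
  krange <- seq(min(ks), max(ks))
  hist_df <- data.frame(bin = vapply(krange, .mfe_bin_label, character(1)),
                        stringsAsFactors = FALSE)
  for (rg in REGION_LEVELS) {
    hist_df[[rg]] <- vapply(krange, function(k) {
      sum(ks == k & interactions$region == rg)
    }, integer(1))
  }
  hist_df$total <- as.integer(rowSums(hist_df[, REGION_LEVELS]))
  list(region_counts = region_counts, mfe_histogram = hist_df)
}

#' Collapse interactions to unique protein-coding genes
#'
#' Drops non-coding (NCRNA) interactions, then keeps one summary per gene
#' symbol, removing transcript isoforms. The representative interaction is
#' the one with minimum MFE (the strongest predicted binding); ties are
#' broken by `(transcript_id, site_start)` lexicographically.
#'
#' @param interactions Interaction data frame.
#' @return A data frame with one row per gene: `gene_symbol`, the
#'   representative interaction's `mirna_id`, `transcript_id`, `region`,
#'   `site_start`, `mfe`, plus `n_sites` (member interactions) and
#'   `mirna_ids` (comma-joined sorted set of targeting miRNAs), ordered
#'   by `gene_symbol`.
#' @export
dedup_genes <- function(interactions) {
  coding <- interactions[interactions$region != "NCRNA", , drop = FALSE]
  if (nrow(coding) == 0L) {
    return(data.frame(gene_symbol = character(0), mirna_id = character(0),
                      transcript_id = character(0), region = character(0),
                      site_start = integer(0), mfe = numeric(0),
                      n_sites = integer(0), mirna_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(coding$gene_symbol, coding$mfe, coding$transcript_id,
               coding$site_start, coding$mirna_id)
  coding <- coding[ord, , drop = FALSE]
  first <- !duplicated(coding$gene_symbol)
  out <- coding[first, c("gene_symbol", "mirna_id", "transcript_id",
                         "region", "site_start", "mfe"), drop = FALSE]
  n_sites <- table(coding$gene_symbol)
  out$n_sites <- as.integer(n_sites[out$gene_symbol])
  out$mirna_ids <- vapply(out$gene_symbol, function(g) {
    paste(sort(unique(coding$mirna_id[coding$gene_symbol == g])), collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}
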