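#' Seed mimicry between plant and host miRNAs
#'
#' Reports every cross pair of a plant miRNA and a host miRNA whose seed
#' regions (nucleotides 2-7) are character-identical -- the sequence-level
#' signature of potential functional mimicry, where an exogenous dietary
#' miRNA engages the same target sites as an endogenous one.
#'
#' @param plant_mirnas,host_mirnas Data frames with `mirna_id` and
#'   `sequence` columns (all sequences >= 7 nt).
#' @return A data frame with columns `plant_mirna_id`, `host_mirna_id`,
#'   `shared_seed`, ordered by `(plant_mirna_id, host_mirna_id)`;
#'   invariant under permutation of either input.
#' @export
find_seed_mimics <- function(plant_mirnas, host_mirnas) {
  empty <- data.frame(plant_mirna_id = character(0),
                      host_mirna_id = character(0),
                      shared_seed = character(0), stringsAsFactors = FALSE)
  if (nrow(plant_mirnas) == 0L || nrow(host_mirnas) == 0L) return(empty)
  if (any(nchar(plant_mirnas$sequence) < 7L) ||
      any(nchar(host_mirnas$sequence) < 7L)) {
    stop("all miRNAs must be >= 7 nt to define a seed")
  }
  ps <- seed_region(plant_mirnas$sequence)
  hs <- seed_region(host_mirnas$sequence)
  hits <- which(outer(ps, hs, `==`), arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(plant_mirna_id = plant_mirnas$mirna_id[hits[, 1]],
                    host_mirna_id = host_mirnas$mirna_id[hits[, 2]],
                    shared_seed = ps[hits[, 1]], stringsAsFactors = FALSE)
  out <- out[order(out$plant_mirna_id, out$host_mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-hybridize seed-mimicking host miRNAs against targeted transcripts
#'
#' For every mimicry pair, the host miRNA is hybridized (perfect
#' Watson-Crick seed, no seed G:U, no energy threshold) against each
#' transcript that the paired plant miRNA was predicted to target. A host
#' miRNA shares only the 6-nt seed, so its binding may be much weaker than
#' the plant miRNA's; all structures found are reported regardless of MFE.
#' Host/transcript combinations with no admissible structure yield no row.
#'
#' @param pairs Mimicry pairs from [find_seed_mimics()].
#' @param interactions Plant-miRNA interaction data frame (the accepted
#'   pipeline predictions); NCRNA rows are ignored.
#' @param transcripts Transcriptome data frame.
#' @param host_mirnas Host miRNA table (provides the host sequences).
#' @param params Energy parameters for [hybridize()].
#' @return A data frame with columns `host_mirna_id`, `plant_mirna_id`,
#'   `transcript_id`, `gene_symbol`, `region`, `mfe`; every row has a
#'   perfect, wobble-free seed. Region is classified at the 5'-most
#'   window position paired within the seed.
#' @export
mimic_hybridize <- function(pairs, interactions, transcripts, host_mirnas,
                            params = default_energy_parameters()) {
  empty <- data.frame(host_mirna_id = character(0), plant_mirna_id = character(0),
                      transcript_id = character(0), gene_symbol = character(0),
                      region = character(0), mfe = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || nrow(interactions) == 0L) return(empty)
  coding <- interactions[interactions$region != "NCRNA", , drop = FALSE]
  rows <- list()
  done <- character(0)
  for (r in seq_len(nrow(pairs))) {
    plant <- pairs$plant_mirna_id[r]
    host <- pairs$host_mirna_id[r]
    host_seq <- host_mirnas$sequence[match(host, host_mirnas$mirna_id)]
    if (is.na(host_seq)) stop("unknown host miRNA: ", host)
    txs <- unique(coding$transcript_id[coding$mirna_id == plant])
    for (tx in txs) {
      key <- paste(host, tx, sep = "\r")
      if (key %in% done) next
      done <- c(done, key)
      ti <- match(tx, transcripts$transcript_id)
      if (is.na(ti)) stop("unknown transcript: ", tx)
      dup <- hybridize(host_seq, transcripts$sequence[ti], params,
                       require_seed_wc = TRUE, forbid_seed_gu = TRUE)
      if (dup$status != "ok") next
      seed_js <- dup$pairs[dup$pairs[, 1] %in% 2:7, 2]
      region <- classify_region(transcripts[ti, ], min(seed_js) - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        host_mirna_id = host, plant_mirna_id = plant, transcript_id = tx,
        gene_symbol = transcripts$gene_symbol[ti], region = region,
        mfe = dup$mfe, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$host_mirna_id, out$transcript_id, out$plant_mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species conservation of mature miRNA sequences
#'
#' For each query miRNA, finds every record in a multi-species mature
#' collection whose full mature sequence is character-identical (after
#' RNA-alphabet normalization) and belongs to a different species. Queries
#' with no such match are reported as not detected.
#'
#' @param query_mirnas Data frame with `mirna_id`, `species`, `sequence`.
#' @param multispecies_mirnas Data frame in the same layout, e.g. from
#'   [read_mirna_fasta()] on a miRBase-style mature-sequence file.
#' @return A data frame with one row per query: `mirna_id`, `sequence`,
#'   `detected` (logical), `matching_species` (comma-joined sorted set of
#'   other-species codes, or `"Not detected"`), `matching_ids`
#'   (comma-joined sorted identifiers).
#' @export
find_conserved <- function(query_mirnas, multispecies_mirnas) {
  stopifnot(all(c("mirna_id", "species", "sequence") %in% names(query_mirnas)),
            all(c("mirna_id", "species", "sequence") %in% names(multispecies_mirnas)))
  n <- nrow(query_mirnas)
  out <- data.frame(mirna_id = query_mirnas$mirna_id,
                    sequence = query_mirnas$sequence,
                    detected = logical(n),
                    matching_species = character(n),
                    matching_ids = character(n),
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    hit <- multispecies_mirnas$sequence == query_mirnas$sequence[r] &
      multispecies_mirnas$species != query_mirnas$species[r]
    if (any(hit)) {
      out$detected[r] <- TRUE
      out$matching_species[r] <-
        paste(sort(unique(multispecies_mirnas$species[hit])), collapse = ",")
      out$matching_ids[r] <-
        paste(sort(multispecies_mirnas$mirna_id[hit]), collapse = ",")
    } else {
      out$matching_species[r] <- "Not detected"
      out$matching_ids[r] <- ""
    }
  }
  out
}
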