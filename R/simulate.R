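# Synthetic-data generator: emulates the pipeline's five external inputs
# (plant miRNA table, transcriptome FASTA + annotation, host miRNA table,
# multi-species mature FASTA, gene-set GMT) with planted ground truth, so
# that every stage is testable offline against a known answer.

.RNA_BASES <- c("A", "C", "G", "U")
.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# sample() treats a length-1 numeric vector as 1:n; these wrappers never do
.sample1 <- function(v) v[sample.int(length(v), 1L)]
.shuffle <- function(v) v[sample.int(length(v))]

.rand_seq <- function(n, gc = 0.5) {
  paste(sample(.RNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Configuration for the synthetic dataset
#'
#' All stochastic choices flow from `seed`; identical configurations give
#' byte-identical bundles. Defaults describe a desk-scale analogue of the
#' study conditions: a small transcriptome with 5'UTR/CDS/3'UTR structure,
#' plant miRNAs whose read counts straddle the 1400-read filter and whose
#' lengths straddle the 19-25 nt window, planted sites that are exact
#' antisense copies of miRNA nucleotides 2-13 (usually extended 3'-ward to
#' realistic binding strength), decoy sites violating individual criteria,
#' host miRNAs with controlled seed sharing, a multi-species collection
#' with planted exact duplicates, and gene sets with one term enriched
#' among the targeted genes.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param coding_fraction Fraction of genes that are protein-coding.
#' @param isoform_prob Probability that a coding gene gets a second
#'   transcript isoform.
#' @param tx_length_range Min/max transcript length (nt, uniform).
#' @param gc GC fraction of background sequence.
#' @param utr5_frac,cds_frac Fractions of a coding transcript allotted to
#'   the 5'UTR and CDS (remainder is 3'UTR).
#' @param n_plant_mirnas Number of plant miRNAs.
#' @param plant_species,host_species Synthetic species codes.
#' @param mirna_lengths Integer vector the miRNA lengths are sampled
#'   from (includes out-of-range lengths so the QC filter is exercised).
#' @param read_meanlog,read_sdlog Log-normal read-count parameters
#'   (centered on the 1400-read threshold).
#' @param n_reverse_orientation Number of miRNAs flagged as
#'   reverse-oriented (exercises the orientation criterion).
#' @param n_planted_sites Named integer vector: planted true sites per
#'   region (`FIVE_UTR`, `CDS`, `THREE_UTR`, `NCRNA`).
#' @param extend_prob Per-nucleotide probability of extending antisense
#'   complementarity through miRNA positions 14..L.
#' @param n_decoys Named integer vector of decoy sites per class
#'   (`SEED_GU`, `SEED_ONLY`, `SHUFFLED`).
#' @param n_host_mirnas Number of host miRNAs.
#' @param host_seed_share Fraction of host miRNAs built to share a seed
#'   with a site-bearing plant miRNA.
#' @param n_species Number of additional species in the multi-species
#'   collection.
#' @param conserved_fraction Fraction of plant miRNAs duplicated exactly
#'   in at least one other species.
#' @param n_other_species_mirnas Background (non-duplicate) records per
#'   additional species.
#' @param n_gene_sets,gene_set_size Gene-set collection dimensions.
#' @param planted_set_fraction Fraction of the planted set's members drawn
#'   from the targeted genes (the enrichment effect size).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 80L,
                              coding_fraction = 0.8,
                              isoform_prob = 0.25,
                              tx_length_range = c(300L, 1500L),
                              gc = 0.5,
                              utr5_frac = 0.15,
                              cds_frac = 0.55,
                              n_plant_mirnas = 30L,
                              plant_species = "szm",
                              host_species = "shs",
                              mirna_lengths = c(17L, 18L, 19L, 20L, 21L, 21L,
                                                22L, 22L, 23L, 24L, 25L, 26L, 27L),
                              read_meanlog = log(1400),
                              read_sdlog = 1.5,
                              n_reverse_orientation = 2L,
                              n_planted_sites = c(FIVE_UTR = 5L, CDS = 10L,
                                                  THREE_UTR = 12L, NCRNA = 3L),
                              extend_prob = 0.95,
                              n_decoys = c(SEED_GU = 5L, SEED_ONLY = 5L,
                                           SHUFFLED = 5L),
                              n_host_mirnas = 20L,
                              host_seed_share = 0.3,
                              n_species = 4L,
                              conserved_fraction = 0.3,
                              n_other_species_mirnas = 10L,
                              n_gene_sets = 10L,
                              gene_set_size = 20L,
                              planted_set_fraction = 0.8) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              coding_fraction = coding_fraction, isoform_prob = isoform_prob,
              tx_length_range = as.integer(tx_length_range), gc = gc,
              utr5_frac = utr5_frac, cds_frac = cds_frac,
              n_plant_mirnas = as.integer(n_plant_mirnas),
              plant_species = plant_species, host_species = host_species,
              mirna_lengths = as.integer(mirna_lengths),
              read_meanlog = read_meanlog, read_sdlog = read_sdlog,
              n_reverse_orientation = as.integer(n_reverse_orientation),
              n_planted_sites = n_planted_sites, extend_prob = extend_prob,
              n_decoys = n_decoys, n_host_mirnas = as.integer(n_host_mirnas),
              host_seed_share = host_seed_share,
              n_species = as.integer(n_species),
              conserved_fraction = conserved_fraction,
              n_other_species_mirnas = as.integer(n_other_species_mirnas),
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size = as.integer(gene_set_size),
              planted_set_fraction = planted_set_fraction)
  stopifnot(cfg$n_genes >= 1L, cfg$coding_fraction >= 0, cfg$coding_fraction <= 1,
            all(cfg$n_planted_sites >= 0L), all(cfg$n_decoys >= 0L),
            cfg$extend_prob >= 0, cfg$extend_prob <= 1,
            cfg$host_seed_share >= 0, cfg$host_seed_share <= 1,
            cfg$conserved_fraction >= 0, cfg$conserved_fraction <= 1,
            all(names(cfg$n_planted_sites) %in% REGION_LEVELS))
  class(cfg) <- "simulation_config"
  cfg
}

#' Plant an antisense binding site into a transcript sequence
#'
#' Substitutes (never inserts, so annotation spans stay valid) the exact
#' reverse complement of miRNA nucleotides 2-13 at `position` (0-based).
#' With probability `extend_prob` per nucleotide, complementarity is
#' extended contiguously through miRNA positions 14..L, each consuming one
#' transcript position 5'-ward of the site.
#'
#' @param sequence Transcript sequence.
#' @param mirna_sequence Mature miRNA sequence (>= 13 nt).
#' @param position 0-based start of the 12-nt site.
#' @param extend_prob Per-nucleotide extension probability.
#' @return A list with `sequence` (modified), `site_start`, `site_end`
#'   and `n_extended` (number of extension nucleotides substituted).
#' @export
plant_site <- function(sequence, mirna_sequence, position, extend_prob = 0) {
  L <- nchar(mirna_sequence)
  stopifnot(L >= 13L, position >= 0L, position + 12L <= nchar(sequence))
  site <- reverse_complement(extended_seed(mirna_sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[(position + 1L):(position + 12L)] <- strsplit(site, "", fixed = TRUE)[[1]]
  n_ext <- 0L
  if (L > 13L && extend_prob > 0) {
    for (t in 14L:L) {
      if (stats::runif(1) >= extend_prob) break
      tpos <- position - (t - 13L)   # 0-based transcript position
      if (tpos < 0L) break
      chars[tpos + 1L] <- .COMPLEMENT[[substr(mirna_sequence, t, t)]]
      n_ext <- n_ext + 1L
    }
  }
  list(sequence = paste(chars, collapse = ""), site_start = as.integer(position),
       site_end = as.integer(position + 12L), n_extended = n_ext)
}

# region span (0-based half-open) of a transcript row
.region_span <- function(tx, region) {
  len <- nchar(tx$sequence)
  switch(region,
         NCRNA = c(0L, len),
         FIVE_UTR = c(0L, tx$cds_start),
         CDS = c(tx$cds_start, tx$cds_end),
         THREE_UTR = c(tx$cds_end, len))
}

# decoy 12-mers ------------------------------------------------------------

.decoy_site <- function(mirna_sequence, class) {
  site <- reverse_complement(extended_seed(mirna_sequence))
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  if (class == "SEED_GU") {
    # corrupt one target base opposite the seed (12-mer indices 7..12
    # face miRNA nucleotides 7..2), creating a G:U wobble where possible
    # and a mismatch otherwise
    idx <- sample(7:12, 1)
    mb <- substr(mirna_sequence, 13L - (idx - 1L), 13L - (idx - 1L))
    chars[idx] <- switch(mb, G = "U", U = "G", A = "C", C = "A")
  } else if (class == "SEED_ONLY") {
    # keep only the seed complement (indices 7..12); randomize the
    # extended half and force >= 1 mismatch there
    repeat {
      rand6 <- sample(.RNA_BASES, 6, replace = TRUE)
      if (!identical(paste(rand6, collapse = ""), substr(site, 1, 6))) break
    }
    chars[1:6] <- rand6
  } else if (class == "SHUFFLED") {
    repeat {
      perm <- sample(chars)
      if (!identical(perm, chars)) break
    }
    chars <- perm
  } else {
    stop("unknown decoy class: ", class)
  }
  paste(chars, collapse = "")
}

# choose a transcript and position for a site of total reach `reach`
# (extension room) in the given region, avoiding occupied intervals
.place_site <- function(transcripts, region, reach, occupied, tries = 60L) {
  cand <- if (region == "NCRNA") {
    which(transcripts$biotype == "noncoding")
  } else {
    which(transcripts$biotype == "coding")
  }
  cand <- .shuffle(cand)
  for (ti in cand) {
    span <- .region_span(transcripts[ti, ], region)
    pos_min <- span[1] + reach
    pos_max <- span[2] - 12L
    if (pos_min > pos_max) next
    occ <- occupied[[transcripts$transcript_id[ti]]]
    for (t in seq_len(tries)) {
      pos <- .sample1(pos_min:pos_max)
      lo <- pos - reach
      hi <- pos + 12L
      clash <- FALSE
      if (!is.null(occ) && nrow(occ) > 0L) {
        clash <- any(lo < occ$hi & hi > occ$lo)
      }
      if (!clash) {
        return(list(tx_index = ti, position = pos, lo = lo, hi = hi))
      }
    }
  }
  stop(sprintf("no transcript has room for a site in region %s", region))
}

#' Generate the full synthetic dataset bundle
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_bundle` with elements `mirnas`,
#'   `transcripts`, `host_mirnas`, `multispecies`, `gene_sets` (named
#'   list), `background` (coding gene universe), `truth` (list: `sites`
#'   data frame with decoy classes, `seed_pairs`, `conserved`,
#'   `enriched_term`), `config` and `log` (character lines).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  # --- transcriptome -------------------------------------------------
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  n_coding <- round(config$n_genes * config$coding_fraction)
  biotype_gene <- c(rep("coding", n_coding),
                    rep("noncoding", config$n_genes - n_coding))
  tx_rows <- list()
  for (g in seq_len(config$n_genes)) {
    n_iso <- 1L + (biotype_gene[g] == "coding" &&
                     stats::runif(1) < config$isoform_prob)
    for (iso in seq_len(n_iso)) {
      len <- sample(config$tx_length_range[1]:config$tx_length_range[2], 1)
      seq <- .rand_seq(len, config$gc)
      if (biotype_gene[g] == "coding") {
        cds_start <- as.integer(round(len * config$utr5_frac))
        cds_end <- as.integer(cds_start + round(len * config$cds_frac))
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = "", gene_symbol = genes[g], biotype = "coding",
          sequence = seq, cds_start = cds_start, cds_end = cds_end,
          stringsAsFactors = FALSE)
      } else {
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = "", gene_symbol = genes[g], biotype = "noncoding",
          sequence = seq, cds_start = NA_integer_, cds_end = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  transcripts <- do.call(rbind, tx_rows)
  transcripts$transcript_id <- sprintf("TX%05d", seq_len(nrow(transcripts)))

  # --- plant miRNAs --------------------------------------------------
  lens <- sample(config$mirna_lengths, config$n_plant_mirnas, replace = TRUE)
  mirnas <- data.frame(
    mirna_id = sprintf("%s-miR%03d", config$plant_species,
                       seq_len(config$n_plant_mirnas)),
    species = config$plant_species,
    sequence = vapply(lens, .rand_seq, character(1), gc = config$gc),
    read_count = as.integer(pmin(round(stats::rlnorm(config$n_plant_mirnas,
                                                     config$read_meanlog,
                                                     config$read_sdlog)),
                                 .Machine$integer.max)),
    orientation = "forward", stringsAsFactors = FALSE)
  if (config$n_reverse_orientation > 0L) {
    rev_idx <- sample(config$n_plant_mirnas,
                      min(config$n_reverse_orientation, config$n_plant_mirnas))
    mirnas$orientation[rev_idx] <- "reverse"
  }
  qc_pass <- with(mirnas, read_count > 1400L & nchar(sequence) >= 19L &
                    nchar(sequence) <= 25L & orientation == "forward")
  if (!any(qc_pass)) {
    # guarantee at least one usable miRNA for planting
    mirnas$read_count[1] <- 5000L
    mirnas$orientation[1] <- "forward"
    mirnas$sequence[1] <- .rand_seq(21L, config$gc)
    qc_pass[1] <- TRUE
  }
  pass_idx <- which(qc_pass)

  # --- planted sites and decoys --------------------------------------
  occupied <- list()
  truth_sites <- list()
  note_occupied <- function(tx_id, lo, hi) {
    occ <- occupied[[tx_id]]
    if (is.null(occ)) occ <- data.frame(lo = integer(0), hi = integer(0))
    occupied[[tx_id]] <<- rbind(occ, data.frame(lo = lo, hi = hi))
  }
  for (region in names(config$n_planted_sites)) {
    for (s in seq_len(config$n_planted_sites[[region]])) {
      mi <- .sample1(pass_idx)
      L <- nchar(mirnas$sequence[mi])
      pl <- .place_site(transcripts, region, reach = L - 13L, occupied)
      res <- plant_site(transcripts$sequence[pl$tx_index],
                        mirnas$sequence[mi], pl$position,
                        extend_prob = config$extend_prob)
      transcripts$sequence[pl$tx_index] <- res$sequence
      note_occupied(transcripts$transcript_id[pl$tx_index], pl$lo, pl$hi)
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        mirna_id = mirnas$mirna_id[mi],
        transcript_id = transcripts$transcript_id[pl$tx_index],
        site_start = res$site_start, region = region, class = "NONE",
        n_extended = res$n_extended, stringsAsFactors = FALSE)
    }
  }
  for (class in names(config$n_decoys)) {
    for (s in seq_len(config$n_decoys[[class]])) {
      mi <- .sample1(pass_idx)
      region <- sample(c("FIVE_UTR", "CDS", "THREE_UTR"), 1)
      pl <- .place_site(transcripts, region, reach = 0L, occupied)
      decoy <- .decoy_site(mirnas$sequence[mi], class)
      seq0 <- transcripts$sequence[pl$tx_index]
      substr(seq0, pl$position + 1L, pl$position + 12L) <- decoy
      transcripts$sequence[pl$tx_index] <- seq0
      note_occupied(transcripts$transcript_id[pl$tx_index], pl$lo, pl$hi)
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        mirna_id = mirnas$mirna_id[mi],
        transcript_id = transcripts$transcript_id[pl$tx_index],
        site_start = pl$position, region = region, class = class,
        n_extended = 0L, stringsAsFactors = FALSE)
    }
  }
  truth_sites <- do.call(rbind, c(truth_sites,
                                  list(data.frame(mirna_id = character(0),
                                                  transcript_id = character(0),
                                                  site_start = integer(0),
                                                  region = character(0),
                                                  class = character(0),
                                                  n_extended = integer(0),
                                                  stringsAsFactors = FALSE))))

  # --- host miRNAs ---------------------------------------------------
  planted_mirna_ids <- unique(truth_sites$mirna_id[truth_sites$class == "NONE"])
  plant_seeds <- unique(seed_region(mirnas$sequence[nchar(mirnas$sequence) >= 7]))
  n_share <- round(config$host_seed_share * config$n_host_mirnas)
  n_share <- min(n_share, config$n_host_mirnas)
  host_rows <- list()
  for (h in seq_len(config$n_host_mirnas)) {
    if (h <= n_share && length(planted_mirna_ids) > 0L) {
      partner <- .sample1(planted_mirna_ids)
      pseq <- mirnas$sequence[mirnas$mirna_id == partner]
      hseq <- .rand_seq(22L, config$gc)
      substr(hseq, 2L, 7L) <- seed_region(pseq)
    } else {
      repeat {
        hseq <- .rand_seq(22L, config$gc)
        if (!(seed_region(hseq) %in% plant_seeds)) break
      }
    }
    host_rows[[h]] <- data.frame(
      mirna_id = sprintf("%s-miR%03d", config$host_species, h),
      species = config$host_species, sequence = hseq,
      read_count = NA_integer_, orientation = "forward",
      stringsAsFactors = FALSE)
  }
  host_mirnas <- do.call(rbind, host_rows)
  # expected mimicry pairs, by direct seed comparison (independent of the
  # detector's implementation)
  hit <- which(outer(substr(mirnas$sequence, 2, 7),
                     substr(host_mirnas$sequence, 2, 7), `==`),
               arr.ind = TRUE)
  truth_seed_pairs <- data.frame(
    plant_mirna_id = mirnas$mirna_id[hit[, 1]],
    host_mirna_id = host_mirnas$mirna_id[hit[, 2]],
    shared_seed = substr(mirnas$sequence[hit[, 1]], 2, 7),
    stringsAsFactors = FALSE)
  truth_seed_pairs <- truth_seed_pairs[order(truth_seed_pairs$plant_mirna_id,
                                             truth_seed_pairs$host_mirna_id), ,
                                       drop = FALSE]
  rownames(truth_seed_pairs) <- NULL

  # --- multi-species collection --------------------------------------
  other_species <- sprintf("sp%s", letters[seq_len(config$n_species)])
  multi_rows <- list(mirnas[, c("mirna_id", "species", "sequence")])
  n_cons <- round(config$conserved_fraction * config$n_plant_mirnas)
  cons_idx <- if (n_cons > 0L) sample(config$n_plant_mirnas, n_cons) else integer(0)
  truth_cons <- list()
  for (ci in cons_idx) {
    k_sp <- sample(seq_len(min(2L, config$n_species)), 1)
    sps <- sample(other_species, k_sp)
    for (sp in sps) {
      multi_rows[[length(multi_rows) + 1L]] <- data.frame(
        mirna_id = sub(paste0("^", config$plant_species), sp,
                       mirnas$mirna_id[ci]),
        species = sp, sequence = mirnas$sequence[ci],
        stringsAsFactors = FALSE)
    }
    truth_cons[[length(truth_cons) + 1L]] <- data.frame(
      mirna_id = mirnas$mirna_id[ci],
      matching_species = paste(sort(sps), collapse = ","),
      stringsAsFactors = FALSE)
  }
  plant_seqs <- mirnas$sequence
  for (sp in other_species) {
    for (b in seq_len(config$n_other_species_mirnas)) {
      repeat {
        bseq <- .rand_seq(sample(19:24, 1), config$gc)
        if (!(bseq %in% plant_seqs)) break
      }
      multi_rows[[length(multi_rows) + 1L]] <- data.frame(
        mirna_id = sprintf("%s-bg%03d", sp, b), species = sp,
        sequence = bseq, stringsAsFactors = FALSE)
    }
  }
  multispecies <- do.call(rbind, multi_rows)
  truth_conserved <- do.call(rbind, c(truth_cons,
                                      list(data.frame(mirna_id = character(0),
                                                      matching_species = character(0),
                                                      stringsAsFactors = FALSE))))

  # --- gene sets -----------------------------------------------------
  background <- sort(unique(transcripts$gene_symbol[transcripts$biotype == "coding"]))
  coding_tx <- transcripts$transcript_id[transcripts$biotype == "coding"]
  targeted <- sort(unique(transcripts$gene_symbol[
    match(truth_sites$transcript_id[truth_sites$class == "NONE" &
                                      truth_sites$transcript_id %in% coding_tx],
          transcripts$transcript_id)]))
  gene_sets <- list()
  set_size <- min(config$gene_set_size, length(background))
  n_from_targeted <- min(round(config$planted_set_fraction * set_size),
                         length(targeted))
  planted_members <- c(sample(targeted, n_from_targeted),
                       sample(setdiff(background, targeted),
                              set_size - n_from_targeted))
  gene_sets[["SIMSET01"]] <- sort(planted_members)
  for (si in seq_len(config$n_gene_sets - 1L)) {
    gene_sets[[sprintf("SIMSET%02d", si + 1L)]] <-
      sort(sample(background, set_size))
  }

  # --- run log -------------------------------------------------------
  tx_lens <- nchar(transcripts$sequence)
  exp_bg <- length(pass_idx) * sum(pmax(tx_lens - 11L, 0L)) / 4^12
  log_lines <- c(
    sprintf("synthetic bundle: seed %d", config$seed),
    sprintf("transcripts: %d (%d coding, %d noncoding) over %d genes",
            nrow(transcripts), sum(transcripts$biotype == "coding"),
            sum(transcripts$biotype == "noncoding"), config$n_genes),
    sprintf("plant miRNAs: %d (%d pass QC)", nrow(mirnas), length(pass_idx)),
    sprintf("planted sites: %d true, %d decoys",
            sum(truth_sites$class == "NONE"), sum(truth_sites$class != "NONE")),
    sprintf("expected spontaneous background 12-mer matches ((L-11)/4^12 per kept miRNA-transcript pair): %.4f",
            exp_bg),
    sprintf("host miRNAs: %d (%d seed-sharing)", nrow(host_mirnas), n_share),
    sprintf("multi-species records: %d over %d species; %d planted duplicates",
            nrow(multispecies), length(unique(multispecies$species)), n_cons),
    sprintf("gene sets: %d of size %d; planted term SIMSET01 (%d/%d members targeted)",
            length(gene_sets), set_size, n_from_targeted, set_size))

  structure(list(mirnas = mirnas, transcripts = transcripts,
                 host_mirnas = host_mirnas, multispecies = multispecies,
                 gene_sets = gene_sets, background = background,
                 truth = list(sites = truth_sites,
                              seed_pairs = truth_seed_pairs,
                              conserved = truth_conserved,
                              enriched_term = "SIMSET01"),
                 config = config, log = log_lines),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits `mirnas.tsv`, `transcripts.fa`, `annotation.tsv`,
#' `host_mirnas.tsv`, `multispecies.fa`, `gene_sets.gmt`, the ground-truth
#' tables (`truth_sites.tsv`, `truth_seed_pairs.tsv`,
#' `truth_conserved.tsv`) and a human-readable `sim_log.txt`.
#'
#' @param bundle A `sim_bundle` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(bundle$mirnas, "mirnas.tsv")
  fa <- Biostrings::RNAStringSet(bundle$transcripts$sequence)
  names(fa) <- bundle$transcripts$transcript_id
  Biostrings::writeXStringSet(fa, file.path(dir, "transcripts.fa"))
  ann <- bundle$transcripts[, c("transcript_id", "gene_symbol", "biotype",
                                "cds_start", "cds_end")]
  w(ann, "annotation.tsv")
  w(bundle$host_mirnas, "host_mirnas.tsv")
  mfa <- Biostrings::RNAStringSet(bundle$multispecies$sequence)
  names(mfa) <- bundle$multispecies$mirna_id
  Biostrings::writeXStringSet(mfa, file.path(dir, "multispecies.fa"))
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  w(bundle$truth$sites, "truth_sites.tsv")
  w(bundle$truth$seed_pairs, "truth_seed_pairs.tsv")
  w(bundle$truth$conserved, "truth_conserved.tsv")
  writeLines(bundle$log, file.path(dir, "sim_log.txt"))
  invisible(dir)
}
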