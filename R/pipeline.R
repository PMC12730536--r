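#' Configuration for an end-to-end pipeline run
#'
#' Validates input paths and thresholds up front. The gene-set, host-miRNA
#' and multi-species inputs are optional; their stages are skipped when
#' absent.
#'
#' @param mirna_path Plant miRNA TSV (see [read_mirna_table()]).
#' @param transcripts_fasta,annotation_path Transcriptome inputs (see
#'   [read_transcriptome()]).
#' @param out_dir Output directory; every stage persists its table here so
#'   stages are individually inspectable and re-runnable.
#' @param gmt_paths Optional character vector of GMT files; each
#'   collection is tested (and FDR-adjusted) independently.
#' @param host_mirna_path Optional host miRNA TSV for the seed-mimicry
#'   stage.
#' @param multispecies_fasta Optional multi-species mature FASTA for the
#'   conservation stage.
#' @param min_reads,min_len,max_len,require_read_counts miRNA QC
#'   thresholds (see [filter_mirnas()]).
#' @param mfe_threshold Strict MFE acceptance threshold, kcal/mol
#'   (must be < 0).
#' @param flank Window slack for [make_window()].
#' @param top_k,fdr_cut Enrichment report settings.
#' @param energy_params An [energy_parameters()] object.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_path, transcripts_fasta, annotation_path,
                            out_dir, gmt_paths = NULL, host_mirna_path = NULL,
                            multispecies_fasta = NULL,
                            min_reads = 1400L, min_len = 19L, max_len = 25L,
                            require_read_counts = TRUE,
                            mfe_threshold = -25.0, flank = 10L,
                            top_k = 10L, fdr_cut = 0.05,
                            energy_params = default_energy_parameters()) {
  paths <- c(mirna_path, transcripts_fasta, annotation_path, gmt_paths,
             host_mirna_path, multispecies_fasta)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(mfe_threshold < 0, flank >= 0L)
  structure(list(mirna_path = mirna_path,
                 transcripts_fasta = transcripts_fasta,
                 annotation_path = annotation_path, out_dir = out_dir,
                 gmt_paths = gmt_paths, host_mirna_path = host_mirna_path,
                 multispecies_fasta = multispecies_fasta,
                 min_reads = min_reads, min_len = min_len, max_len = max_len,
                 require_read_counts = require_read_counts,
                 mfe_threshold = mfe_threshold, flank = flank,
                 top_k = top_k, fdr_cut = fdr_cut,
                 energy_params = energy_params),
            class = "pipeline_config")
}

#' Score candidate sites and keep those passing the selection criteria
#'
#' For each seed-anchored candidate site, a target window is extracted
#' with [make_window()], hybridized with the seed constraints active, and
#' retained iff [passes_criteria()] holds (perfect Watson-Crick seed, no
#' seed G:U, MFE strictly below the threshold).
#'
#' @param sites Candidate sites from [find_sites()].
#' @param mirnas miRNA table supplying the sequences.
#' @param transcripts Transcriptome data frame.
#' @param params Energy parameters.
#' @param mfe_threshold Strict acceptance threshold, kcal/mol (`NA`
#'   disables it).
#' @param flank Window slack, nucleotides.
#' @return The accepted subset of `sites` with columns `mirna_id`,
#'   `transcript_id`, `site_start`, `mfe`.
#' @export
score_sites <- function(sites, mirnas, transcripts,
                        params = default_energy_parameters(),
                        mfe_threshold = -25.0, flank = 10L) {
  accepted <- list()
  for (r in seq_len(nrow(sites))) {
    mseq <- mirnas$sequence[match(sites$mirna_id[r], mirnas$mirna_id)]
    ti <- match(sites$transcript_id[r], transcripts$transcript_id)
    if (is.na(mseq) || is.na(ti)) {
      stop("site references unknown miRNA or transcript at row ", r)
    }
    win <- make_window(transcripts[ti, ], sites[r, ], nchar(mseq),
                       flank = flank)
    dup <- hybridize(mseq, win$sequence, params,
                     require_seed_wc = TRUE, forbid_seed_gu = TRUE)
    if (passes_criteria(dup, mfe_threshold)) {
      accepted[[length(accepted) + 1L]] <-
        cbind(sites[r, c("mirna_id", "transcript_id", "site_start")],
              mfe = dup$mfe)
    }
  }
  out <- do.call(rbind, c(accepted,
                          list(data.frame(mirna_id = character(0),
                                          transcript_id = character(0),
                                          site_start = integer(0),
                                          mfe = numeric(0),
                                          stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Run the full target-prediction pipeline
#'
#' Fixed stage order: miRNA QC, seed-anchored site search, constrained
#' duplex evaluation, region annotation and gene-level deduplication,
#' over-representation analysis, seed mimicry and conservation. Each
#' stage's table is written to `out_dir`; the run is fully deterministic,
#' so rerunning on identical inputs gives byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `qc`, `sites`, `interactions`,
#'   `summary`, `genes`, `enrichment` (named list per GMT file),
#'   `mimicry` (list: `pairs`, `hybridizations`), `conservation` and
#'   `log` (character lines, also written to `run_log.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # stage 1: miRNA QC
  mirnas <- read_mirna_table(config$mirna_path)
  qc <- filter_mirnas(mirnas, min_reads = config$min_reads,
                      min_len = config$min_len, max_len = config$max_len,
                      require_read_counts = config$require_read_counts)
  write_qc_report(qc, file.path(out, "kept_mirnas.tsv"),
                  file.path(out, "rejected_mirnas.tsv"))
  note("qc: %d miRNAs in, %d kept, %d rejected",
       nrow(mirnas), nrow(qc$kept), nrow(qc$rejected))

  # stage 2: seed-anchored site search
  transcripts <- read_transcriptome(config$transcripts_fasta,
                                    config$annotation_path)
  sites <- find_sites(qc$kept, transcripts)
  wtsv(sites, "sites.tsv")
  note("site_search: %d kept miRNAs vs %d transcripts -> %d candidate sites",
       nrow(qc$kept), nrow(transcripts), nrow(sites))

  # stage 3: constrained duplex evaluation
  accepted <- score_sites(sites, qc$kept, transcripts,
                          params = config$energy_params,
                          mfe_threshold = config$mfe_threshold,
                          flank = config$flank)
  note("duplex: %d of %d sites pass (seed WC, no seed G:U, MFE < %.1f)",
       nrow(accepted), nrow(sites), config$mfe_threshold)

  # stage 4: annotation, summary, gene-level deduplication
  interactions <- annotate_interactions(accepted, transcripts)
  write_interactions_tsv(interactions, file.path(out, "interactions.tsv"))
  write_edges_tsv(interactions, file.path(out, "edges.tsv"))
  summ <- summarize_interactions(interactions)
  wtsv(data.frame(region = names(summ$region_counts),
                  count = as.integer(summ$region_counts)),
       "region_summary.tsv")
  wtsv(summ$mfe_histogram, "mfe_histogram.tsv")
  genes <- dedup_genes(interactions)
  wtsv(genes, "gene_summaries.tsv")
  note("annotate: regions %s",
       paste(sprintf("%s=%d", names(summ$region_counts), summ$region_counts),
             collapse = " "))
  note("dedup: %d interactions -> %d unique protein-coding genes",
       nrow(interactions), nrow(genes))

  # stage 5: over-representation analysis
  background <- sort(unique(transcripts$gene_symbol[transcripts$biotype == "coding"]))
  enrichment <- list()
  for (gp in config$gmt_paths) {
    sets <- read_gmt(gp)
    res <- enrich(genes$gene_symbol, sets, background,
                  top_k = config$top_k, fdr_cut = config$fdr_cut)
    cname <- tools::file_path_sans_ext(basename(gp))
    enrichment[[cname]] <- res
    wtsv(res$table, sprintf("enrichment_%s.tsv", cname))
    note("enrich[%s]: %d sets, %d reported at FDR < %g (%d query genes outside background)",
         cname, nrow(res$table), nrow(res$report), config$fdr_cut,
         res$n_query_dropped)
  }

  # stage 6: seed mimicry and re-hybridization
  mimicry <- NULL
  if (!is.null(config$host_mirna_path)) {
    hosts <- read_mirna_table(config$host_mirna_path)
    plant_hit <- qc$kept[qc$kept$mirna_id %in% interactions$mirna_id, ,
                         drop = FALSE]
    pairs <- find_seed_mimics(plant_hit, hosts)
    hyb <- mimic_hybridize(pairs, interactions, transcripts, hosts,
                           params = config$energy_params)
    wtsv(pairs, "mimicry_pairs.tsv")
    wtsv(hyb, "mimic_hybridizations.tsv")
    mimicry <- list(pairs = pairs, hybridizations = hyb)
    note("mimicry: %d seed-identical pairs, %d host hybridizations (no MFE cutoff)",
         nrow(pairs), nrow(hyb))
  }

  # stage 7: cross-species conservation
  conservation <- NULL
  if (!is.null(config$multispecies_fasta)) {
    multi <- read_mirna_fasta(config$multispecies_fasta)
    queries <- qc$kept[qc$kept$mirna_id %in% interactions$mirna_id, ,
                       drop = FALSE]
    conservation <- find_conserved(queries, multi)
    wtsv(conservation, "conservation.tsv")
    note("conservation: %d of %d interacting miRNAs found in other species",
         sum(conservation$detected), nrow(conservation))
  }

  writeLines(log_lines, file.path(out, "run_log.txt"))
  writeLines(pipeline_report(interactions, genes),
             file.path(out, "report.txt"))
  invisible(list(qc = qc, sites = sites, interactions = interactions,
                 summary = summ, genes = genes, enrichment = enrichment,
                 mimicry = mimicry, conservation = conservation,
                 log = log_lines))
}

#' Plain-text summary report of an interaction set
#'
#' Region counts, the 5-kcal/mol MFE histogram per region, and per-miRNA
#' target-gene counts.
#'
#' @param interactions Interaction data frame.
#' @param gene_summaries Output of [dedup_genes()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(interactions, gene_summaries) {
  summ <- summarize_interactions(interactions)
  lines <- c(sprintf("interactions: %d", nrow(interactions)),
             "region counts:",
             sprintf("  %s: %d", names(summ$region_counts),
                     summ$region_counts),
             "MFE histogram (kcal/mol bins):")
  h <- summ$mfe_histogram
  for (r in seq_len(nrow(h))) {
    lines <- c(lines, sprintf("  %s: %s total=%d", h$bin[r],
                              paste(sprintf("%s=%d", REGION_LEVELS,
                                            unlist(h[r, REGION_LEVELS])),
                                    collapse = " "), h$total[r]))
  }
  lines <- c(lines, sprintf("unique protein-coding genes: %d",
                            nrow(gene_summaries)))
  if (nrow(interactions) > 0L) {
    coding <- interactions[interactions$region != "NCRNA", , drop = FALSE]
    per_mirna <- sort(tapply(coding$gene_symbol, coding$mirna_id,
                             function(g) length(unique(g))), decreasing = TRUE)
    lines <- c(lines, "target genes per miRNA:",
               sprintf("  %s: %d", names(per_mirna), per_mirna))
  }
  lines
}
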