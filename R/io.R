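#' Read a mature miRNA table
#'
#' The authoritative dialect is a tab-separated file with a header line and
#' columns `mirna_id`, `species`, `sequence`, and optionally `read_count`
#' (non-negative integer; deep-sequencing support) and `orientation`
#' (`"forward"` or `"reverse"`, default forward). Sequences are normalized
#' to the RNA alphabet on read. miRBase-style FASTA input is supported by
#' [read_mirna_fasta()].
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `mirna_id`, `species`, `sequence`,
#'   `read_count` (NA when absent from the file) and `orientation`.
#' @export
read_mirna_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) {
    return(data.frame(mirna_id = character(0), species = character(0),
                      sequence = character(0), read_count = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  required <- c("mirna_id", "species", "sequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("miRNA table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- df$mirna_id[duplicated(df$mirna_id)]
  if (length(dup) > 0L) {
    stop("duplicate mirna_id in miRNA table: ", paste(unique(dup), collapse = ", "))
  }
  df$sequence <- normalize_sequences(df$sequence)
  if ("read_count" %in% names(df)) {
    rc <- suppressWarnings(as.integer(df$read_count))
    if (any(is.na(rc) & nzchar(df$read_count) & !is.na(df$read_count))) {
      stop("non-integer read_count value in miRNA table")
    }
    if (any(!is.na(rc) & rc < 0L)) stop("negative read_count in miRNA table")
    df$read_count <- rc
  } else {
    df$read_count <- NA_integer_
  }
  if (!"orientation" %in% names(df)) {
    df$orientation <- "forward"
  } else {
    df$orientation[is.na(df$orientation) | !nzchar(df$orientation)] <- "forward"
    bad <- setdiff(unique(df$orientation), c("forward", "reverse"))
    if (length(bad) > 0L) stop("invalid orientation value(s): ", paste(bad, collapse = ", "))
  }
  df[, c("mirna_id", "species", "sequence", "read_count", "orientation")]
}

#' Read mature miRNAs from a miRBase-dialect FASTA file
#'
#' Convenience reader for multi-species mature-sequence FASTA files in the
#' miRBase `mature.fa` dialect: the record identifier is the first
#' whitespace-separated token of the header and the species is inferred
#' from its three/four-letter prefix (e.g. `"zma-miR156a"` is species
#' `"zma"`). Read counts are not carried by FASTA headers and are set to
#' `NA`.
#'
#' @param path Path to the FASTA file.
#' @param species Optional character vector (recycled) overriding the
#'   id-prefix species inference.
#' @return A data frame in the [read_mirna_table()] layout.
#' @export
read_mirna_fasta <- function(path, species = NULL) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate mirna_id in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(species)) {
    species <- sub("-.*$", "", ids)
  }
  seqs <- if (length(set) > 0L) normalize_sequences(as.character(set)) else character(0)
  data.frame(mirna_id = ids, species = rep_len(species, length(ids)),
             sequence = seqs,
             read_count = rep(NA_integer_, length(ids)),
             orientation = rep("forward", length(ids)),
             stringsAsFactors = FALSE)
}

#' Read a transcriptome (FASTA plus annotation table)
#'
#' The annotation is a 5-column TSV keyed by `transcript_id` with columns
#' `transcript_id`, `gene_symbol`, `biotype` (`"coding"` or `"noncoding"`)
#' and, for coding transcripts only, `cds_start` and `cds_end` -- a
#' 0-based, half-open CDS span in transcript coordinates. Every FASTA
#' record must have exactly one annotation row and vice versa.
#'
#' @param fasta_path Path to the transcript FASTA file.
#' @param annotation_path Path to the annotation TSV.
#' @return A data frame with columns `transcript_id`, `gene_symbol`,
#'   `biotype`, `sequence`, `cds_start`, `cds_end` (the spans are `NA`
#'   for noncoding transcripts).
#' @export
read_transcriptome <- function(fasta_path, annotation_path) {
  stopifnot(file.exists(fasta_path), file.exists(annotation_path))
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "gene_symbol", "biotype", "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  orphan_fa <- setdiff(ids, ann$transcript_id)
  orphan_ann <- setdiff(ann$transcript_id, ids)
  if (length(orphan_fa) > 0L || length(orphan_ann) > 0L) {
    stop("annotation/FASTA mismatch; FASTA-only: [",
         paste(orphan_fa, collapse = ", "), "]; annotation-only: [",
         paste(orphan_ann, collapse = ", "), "]")
  }
  if (anyDuplicated(ids)) stop("duplicate transcript_id in FASTA")
  if (anyDuplicated(ann$transcript_id)) stop("duplicate transcript_id in annotation")
  seqs <- if (length(set) > 0L) normalize_sequences(as.character(set)) else character(0)
  names(seqs) <- ids
  ann$sequence <- unname(seqs[ann$transcript_id])
  bad_bio <- setdiff(unique(ann$biotype), c("coding", "noncoding"))
  if (length(bad_bio) > 0L) stop("invalid biotype value(s): ", paste(bad_bio, collapse = ", "))
  ann$cds_start <- suppressWarnings(as.integer(ann$cds_start))
  ann$cds_end <- suppressWarnings(as.integer(ann$cds_end))
  nc <- ann$biotype == "noncoding"
  if (any(nc & (!is.na(ann$cds_start) | !is.na(ann$cds_end)))) {
    stop("noncoding transcript(s) carry CDS coordinates: ",
         paste(ann$transcript_id[nc & (!is.na(ann$cds_start) | !is.na(ann$cds_end))],
               collapse = ", "))
  }
  cod <- !nc
  len <- nchar(ann$sequence)
  bad_span <- cod & (is.na(ann$cds_start) | is.na(ann$cds_end) |
                     ann$cds_start < 0L | ann$cds_start >= ann$cds_end |
                     ann$cds_end > len)
  if (any(bad_span)) {
    stop("invalid CDS span (need 0 <= cds_start < cds_end <= length) for: ",
         paste(ann$transcript_id[bad_span], collapse = ", "))
  }
  ann[, c("transcript_id", "gene_symbol", "biotype", "sequence",
          "cds_start", "cds_end")]
}

#' Read a gene-set collection in GMT format
#'
#' One gene set per line: term name, description, then tab-separated gene
#' symbols. Empty sets are rejected.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (term -> member genes).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: need term, description and >=1 gene", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("malformed GMT line %d: empty gene set '%s'", i, fields[1]))
    }
    if (fields[1] %in% names(sets)) {
      stop(sprintf("duplicate term '%s' at GMT line %d", fields[1], i))
    }
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors (term -> member genes).
#' @param path Output path.
#' @param descriptions Optional character vector of per-term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# interaction tables -------------------------------------------------------

interaction_columns <- c("mirna_id", "transcript_id", "gene_symbol",
                         "region", "site_start", "mfe")

#' Write / read an interaction table
#'
#' Tab-separated with one header line; columns `mirna_id`,
#' `transcript_id`, `gene_symbol`, `region`, `site_start` (0-based) and
#' `mfe` (kcal/mol). Writing then reading reproduces all fields exactly
#' (energies are reported at the 0.01 kcal/mol resolution of the
#' parameter tables, so their decimal representation is lossless).
#'
#' @param interactions Data frame of interactions.
#' @param path File path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_interactions_tsv <- function(interactions, path) {
  stopifnot(all(interaction_columns %in% names(interactions)))
  utils::write.table(interactions[, interaction_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions_tsv
#' @export
read_interactions_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(interaction_columns %in% names(df)))
  df$site_start <- as.integer(df$site_start)
  df$mfe <- as.numeric(df$mfe)
  df
}

#' Export interactions as a network edge list
#'
#' One edge per interaction: source miRNA, target gene, MFE and transcript
#' region, suitable for import into network tools.
#'
#' @param interactions Data frame of interactions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(interactions, path) {
  edges <- data.frame(source = interactions$mirna_id,
                      target = interactions$gene_symbol,
                      mfe = interactions$mfe,
                      region = interactions$region,
                      stringsAsFactors = FALSE)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mature maize miRNAs analyzed for prostate-cancer gene targeting
#'
#' The fifteen mature Zea mays miRNA sequences predicted to hybridize with
#' human prostate-cancer-pathway mRNAs, shipped as a small TSV fixture
#' (no read counts; miRBase does not distribute them).
#'
#' @return A data frame in the [read_mirna_table()] layout (15 rows).
#' @export
maize_mirna_fixture <- function() {
  read_mirna_table(system.file("extdata", "zma_pca_mirnas.tsv",
                               package = "xkmir", mustWork = TRUE))
}
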