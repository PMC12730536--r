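#' Filter mature miRNAs by the study's three selection criteria
#'
#' A miRNA is kept iff (1) its deep-sequencing read count is strictly
#' greater than `min_reads` ("more than"), (2) its length lies in the
#' inclusive range `[min_len, max_len]` ("between ... and"), and (3) its
#' reported orientation is forward (5' to 3'). Filtering never fails: every
#' input record lands either in `kept` or in `rejected` with reason codes.
#'
#' @param mirnas Data frame in the [read_mirna_table()] layout.
#' @param min_reads Read-count threshold; strict (default 1400, so a count
#'   of exactly 1400 is rejected).
#' @param min_len,max_len Inclusive length bounds (defaults 19 and 25).
#' @param require_read_counts When `TRUE` (default), records lacking a
#'   read count are rejected with reason `LOW_READS`; set `FALSE` to let
#'   count-free tables (e.g. FASTA-derived) pass criterion (1).
#' @return An object of class `mirna_qc`: a list with `kept` (data frame),
#'   `rejected` (data frame with a `reasons` column holding comma-joined
#'   codes from `LOW_READS`, `BAD_LENGTH`, `BAD_ORIENTATION`) and the
#'   thresholds used.
#' @export
filter_mirnas <- function(mirnas, min_reads = 1400L, min_len = 19L,
                          max_len = 25L, require_read_counts = TRUE) {
  stopifnot(min_reads > 0L, min_len > 0L, min_len <= max_len)
  stopifnot(all(c("mirna_id", "sequence") %in% names(mirnas)))
  n <- nrow(mirnas)
  read_count <- if ("read_count" %in% names(mirnas)) mirnas$read_count else rep(NA_integer_, n)
  orientation <- if ("orientation" %in% names(mirnas)) mirnas$orientation else rep("forward", n)
  len <- nchar(mirnas$sequence)

  low_reads <- if (require_read_counts) {
    is.na(read_count) | read_count <= min_reads
  } else {
    !is.na(read_count) & read_count <= min_reads
  }
  bad_length <- len < min_len | len > max_len
  bad_orientation <- !is.na(orientation) & orientation == "reverse"

  reasons <- mapply(function(lr, bl, bo) {
    paste(c(if (lr) "LOW_READS", if (bl) "BAD_LENGTH",
            if (bo) "BAD_ORIENTATION"), collapse = ",")
  }, low_reads, bad_length, bad_orientation)
  keep <- !(low_reads | bad_length | bad_orientation)

  kept <- mirnas[keep, , drop = FALSE]
  rejected <- mirnas[!keep, , drop = FALSE]
  rejected$reasons <- if (n > 0L) reasons[!keep] else character(0)
  rownames(kept) <- NULL
  rownames(rejected) <- NULL
  structure(list(kept = kept, rejected = rejected,
                 min_reads = min_reads, min_len = min_len, max_len = max_len,
                 require_read_counts = require_read_counts),
            class = "mirna_qc")
}

#' @export
print.mirna_qc <- function(x, ...) {
  cat(sprintf("miRNA QC: %d kept, %d rejected (reads > %d, length %d-%d)\n",
              nrow(x$kept), nrow(x$rejected), x$min_reads, x$min_len, x$max_len))
  if (nrow(x$rejected) > 0L) {
    tab <- sort(table(x$rejected$reasons), decreasing = TRUE)
    for (i in seq_along(tab)) cat(sprintf("  %s: %d\n", names(tab)[i], tab[i]))
  }
  invisible(x)
}

#' Write the kept/rejected tables of a QC report
#'
#' @param qc An object returned by [filter_mirnas()].
#' @param kept_path,rejected_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_qc_report <- function(qc, kept_path, rejected_path) {
  stopifnot(inherits(qc, "mirna_qc"))
  utils::write.table(qc$kept, kept_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$rejected, rejected_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(kept_path, rejected_path))
}
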