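test_that("region classification respects half-open CDS boundaries", {
  tx <- list(biotype = "coding", sequence = strrep("A", 60),
             cds_start = 10L, cds_end = 40L)
  expect_identical(classify_region(tx, 9L), "FIVE_UTR")
  expect_identical(classify_region(tx, 10L), "CDS")
  expect_identical(classify_region(tx, 39L), "CDS")
  expect_identical(classify_region(tx, 40L), "THREE_UTR")
  expect_error(classify_region(tx, 60L), "outside")
  expect_error(classify_region(tx, -1L), "outside")
  nc <- list(biotype = "noncoding", sequence = strrep("A", 60),
             cds_start = NA, cds_end = NA)
  expect_identical(classify_region(nc, 25L), "NCRNA")
})

test_that("summaries conserve counts and bin energies left-closed toward -Inf", {
  mk <- function(regions, mfes) {
    data.frame(mirna_id = "m", transcript_id = "t", gene_symbol = "g",
               region = regions, site_start = 0L, mfe = mfes,
               stringsAsFactors = FALSE)
  }
  s <- summarize_interactions(mk(c("CDS", "CDS", "THREE_UTR"),
                                 c(-26, -31, -36)))
  expect_identical(unname(s$region_counts[c("CDS", "THREE_UTR")]), c(2L, 1L))
  expect_identical(s$mfe_histogram$total, c(1L, 1L, 1L))
  expect_identical(s$mfe_histogram$bin,
                   c("[-25,-30)", "[-30,-35)", "[-35,-40)"))
  # -30.0 belongs to [-30,-35), the more negative bin
  s30 <- summarize_interactions(mk("CDS", -30))
  expect_identical(s30$mfe_histogram$bin, "[-30,-35)")

  empty <- summarize_interactions(mk("CDS", -26)[0, ])
  expect_true(all(empty$region_counts == 0L))

  # conservation at the scale of a transcriptome-wide run:
  # 4749 CDS + 2886 3'UTR + 977 5'UTR + 1781 ncRNA = 10393
  counts <- c(CDS = 4749L, THREE_UTR = 2886L, FIVE_UTR = 977L, NCRNA = 1781L)
  big <- mk(rep(names(counts), counts),
            rep(-26.5, sum(counts)))
  sb <- summarize_interactions(big)
  expect_identical(sb$region_counts[names(counts)], counts)
  expect_identical(sum(sb$region_counts), 10393L)
  expect_identical(sum(sb$mfe_histogram$total), 10393L)
})

test_that("gene deduplication drops ncRNA, collapses isoforms, keeps best MFE", {
  interactions <- data.frame(
    mirna_id = c("m1", "m2", "m1", "m3", "m1"),
    transcript_id = c("t1a", "t1b", "t2", "t2", "t3"),
    gene_symbol = c("G1", "G1", "G2", "G2", "NC1"),
    region = c("CDS", "THREE_UTR", "FIVE_UTR", "FIVE_UTR", "NCRNA"),
    site_start = c(5L, 9L, 2L, 2L, 7L),
    mfe = c(-28, -31.5, -26, -26, -40),
    stringsAsFactors = FALSE)
  g <- dedup_genes(interactions)
  expect_identical(g$gene_symbol, c("G1", "G2"))
  # isoform with the lower MFE represents the gene
  expect_identical(g$mfe, c(-31.5, -26))
  expect_identical(g$transcript_id[1], "t1b")
  # tie at G2 broken by transcript_id, then site_start
  expect_identical(g$mirna_id[2], "m1")
  expect_identical(g$n_sites, c(2L, 2L))
  expect_identical(g$mirna_ids, c("m1,m2", "m1,m3"))

  only_nc <- interactions[interactions$region == "NCRNA", ]
  expect_identical(nrow(dedup_genes(only_nc)), 0L)
})

test_that("fourteen sites over thirteen genes collapse to thirteen summaries", {
  genes <- c(sprintf("G%02d", 1:13), "G03")
  interactions <- data.frame(
    mirna_id = sprintf("m%02d", seq_along(genes)),
    transcript_id = sprintf("t%02d", seq_along(genes)),
    gene_symbol = genes,
    region = "THREE_UTR", site_start = seq_along(genes),
    mfe = seq(-26, -39, length.out = length(genes)),
    stringsAsFactors = FALSE)
  expect_identical(nrow(dedup_genes(interactions)), 13L)
})
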