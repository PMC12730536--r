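test_that("seed mimicry pairs exactly the miRNAs with identical nt 2-7", {
  plant <- make_mirnas("zma-miR528a-5p", "UGGAAGGGGCAUGCAGAGGAG")
  host <- make_mirnas(c("hsa-a", "hsa-b"),
                      c(paste0("A", "GGAAGG", rand_rna(14)),
                        paste0("A", "CCCCCC", rand_rna(14))),
                      species = "hsa")
  pairs <- find_seed_mimics(plant, host)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$host_mirna_id, "hsa-a")
  expect_identical(pairs$shared_seed, "GGAAGG")

  # identical full sequences necessarily share a seed
  twin <- make_mirnas("hsa-twin", plant$sequence, species = "hsa")
  expect_identical(nrow(find_seed_mimics(plant, twin)), 1L)

  none <- find_seed_mimics(plant, host[2, , drop = FALSE])
  expect_identical(nrow(none), 0L)
  expect_error(find_seed_mimics(make_mirnas("x", "ACGUA"), host), ">= 7")
})

test_that("mimicry detection is invariant under permutation of both inputs", {
  set.seed(31)
  plant <- make_mirnas(sprintf("p%d", 1:8),
                       vapply(rep(21, 8), rand_rna, character(1)))
  host <- make_mirnas(sprintf("h%d", 1:8),
                      c(plant$sequence[3], vapply(rep(22, 7), rand_rna,
                                                  character(1))),
                      species = "hsa")
  ref <- find_seed_mimics(plant, host)
  expect_true(nrow(ref) >= 1L)
  shuf <- find_seed_mimics(plant[sample(8), ], host[sample(8), ])
  expect_identical(shuf, ref)
})

test_that("conservation requires exact full-length identity in another species", {
  query <- make_mirnas(c("zma-miR396c", "zma-miR159f-5p"),
                       c("UUCCACAGGCUUUCUUGAACUG", "GAGCUCCUCUCAUUCCAAUGA"))
  multi <- rbind(
    make_mirnas("zma-miR396c", "UUCCACAGGCUUUCUUGAACUG"),
    make_mirnas("sbi-miR396", "UUCCACAGGCUUUCUUGAACUG", species = "sbi"),
    # a single-nucleotide variant does not count
    make_mirnas("osa-miR159", "GAGCUCCUCUCAUUCCAAUGC", species = "osa"))
  hits <- find_conserved(query, multi)
  expect_identical(hits$detected, c(TRUE, FALSE))
  expect_identical(hits$matching_species, c("sbi", "Not detected"))
  expect_identical(hits$matching_ids[1], "sbi-miR396")

  # identity is symmetric: querying the other species finds the first
  back <- find_conserved(multi[2, , drop = FALSE], rbind(query, multi))
  expect_true(back$detected)
  expect_match(back$matching_ids, "zma-miR396c")

  # a collection equal to the query (unique ids per species) yields nothing
  self <- find_conserved(query, query)
  expect_identical(self$matching_species, rep("Not detected", 2))
})

test_that("mimicking hosts re-hybridize against the plant-targeted transcripts", {
  set.seed(55)
  plant <- make_mirnas("szm-p1", "GCUCACUUCUCUCUCUGUCAGU")
  # transcript carrying a strong planted site for the plant miRNA
  seq <- rand_rna(300)
  planted <- plant_site(seq, plant$sequence, 150, extend_prob = 1)
  tx <- make_transcripts("tx1", "G1", "coding", planted$sequence,
                         cds_start = 40L, cds_end = 250L)
  interactions <- data.frame(mirna_id = "szm-p1", transcript_id = "tx1",
                             gene_symbol = "G1", region = "CDS",
                             site_start = 150L, mfe = -30,
                             stringsAsFactors = FALSE)
  # host 1: the identical sequence; host 2: shares only the seed
  hosts <- make_mirnas(c("shs-h1", "shs-h2"),
                       c(plant$sequence, paste0("A", "CUCACU", rand_rna(15))),
                       species = "shs")
  pairs <- find_seed_mimics(plant, hosts)
  expect_identical(nrow(pairs), 2L)
  hyb <- mimic_hybridize(pairs, interactions, tx, hosts)
  expect_true("shs-h1" %in% hyb$host_mirna_id)
  # an identical host reproduces the plant duplex against the transcript
  full <- hybridize(plant$sequence, tx$sequence)
  expect_equal(hyb$mfe[hyb$host_mirna_id == "shs-h1"], full$mfe)
  expect_identical(hyb$region[hyb$host_mirna_id == "shs-h1"], "CDS")
  # weak seed-only hosts are reported (or absent), never filtered by MFE
  expect_true(all(is.finite(hyb$mfe)))

  expect_identical(nrow(mimic_hybridize(pairs[0, ], interactions, tx, hosts)),
                   0L)
})
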