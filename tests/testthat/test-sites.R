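test_that("seed and extended seed are the documented substrings", {
  expect_identical(seed_region("AGAAGAGAGAGAGUACAGCCU"), "GAAGAG")
  expect_identical(seed_region("GCUCACUUCUCUCUCUGUCAGU"), "CUCACU")
  expect_error(seed_region("ACGUAC"), "seed")
  expect_identical(extended_seed("GCUCACUUCUCUCUCUGUCAGU"), "CUCACUUCUCUC")
  expect_identical(extended_seed("UGGAAGGGGCAUGCAGAGGAG"), "GGAAGGGGCAUG")
  expect_error(extended_seed("ACGUACGUACGU"), "extended seed")
})

test_that("reverse complement is the Watson-Crick involution", {
  expect_identical(reverse_complement("CUCACUUCUCUC"), "GAGAGAAGUGAG")
  expect_identical(reverse_complement(""), "")
  set.seed(11)
  for (r in 1:25) {
    x <- rand_rna(sample(1:80, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("a planted antisense 12-mer is found at its exact coordinate", {
  m <- make_mirnas("zma-miR156a-3p", "GCUCACUUCUCUCUCUGUCAGU")
  tx <- make_transcripts("tx1", "G1", "noncoding",
                         paste0(strrep("A", 30), "GAGAGAAGUGAG", strrep("A", 58)))
  hits <- find_sites(m, tx)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_start, 30L)
  expect_identical(hits$site_end, 42L)
  expect_identical(hits$site_sequence, "GAGAGAAGUGAG")
})

test_that("sense-strand identity is never a site", {
  m <- make_mirnas("mir", "GCUCACUUCUCUCUCUGUCAGU")
  tx <- make_transcripts("tx1", "G1", "noncoding",
                         paste0(strrep("A", 20), m$sequence, strrep("A", 20)))
  expect_identical(nrow(find_sites(m, tx)), 0L)
})

test_that("overlapping occurrences are all reported", {
  m <- make_mirnas("zma-miR156a-3p", "GCUCACUUCUCUCUCUGUCAGU")
  # tandem repeat: the 12-mer occurs at 0-based offsets 0 and 9
  tx <- make_transcripts("tx1", "G1", "noncoding", "GAGAGAAGUGAGAGAAGUGAG")
  hits <- find_sites(m, tx)
  expect_identical(hits$site_start, c(0L, 9L))
  expect_identical(hits, naive_find_sites(m, tx))
})

test_that("site search agrees with the naive scan on random inputs", {
  set.seed(23)
  for (r in 1:15) {
    n_mir <- sample(1:4, 1)
    mirnas <- make_mirnas(sprintf("m%d", seq_len(n_mir)),
                          vapply(sample(13:24, n_mir, replace = TRUE),
                                 rand_rna, character(1)))
    n_tx <- sample(1:5, 1)
    seqs <- vapply(sample(50:300, n_tx, replace = TRUE), rand_rna, character(1))
    # plant one guaranteed site so non-empty cases are exercised
    victim <- sample(n_tx, 1)
    pat <- reverse_complement(substr(mirnas$sequence[1], 2, 13))
    substr(seqs[victim], 10, 21) <- pat
    tx <- make_transcripts(sprintf("t%d", seq_len(n_tx)),
                           sprintf("G%d", seq_len(n_tx)),
                           "noncoding", seqs)
    expect_identical(find_sites(mirnas, tx), naive_find_sites(mirnas, tx))
    # adding transcripts never removes matches
    more <- rbind(tx, make_transcripts("textra", "Gx", "noncoding",
                                       rand_rna(100)))
    h1 <- find_sites(mirnas, tx)
    h2 <- find_sites(mirnas, more)
    expect_true(all(paste(h1$mirna_id, h1$transcript_id, h1$site_start) %in%
                      paste(h2$mirna_id, h2$transcript_id, h2$site_start)))
  }
})
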