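test_that("planting substitutes exactly the documented nucleotides", {
  set.seed(61)
  mir <- rand_rna(21)
  seq <- rand_rna(120)
  p0 <- plant_site(seq, mir, 50, extend_prob = 0)
  expect_identical(nchar(p0$sequence), 120L)
  expect_identical(substr(p0$sequence, 51, 62),
                   reverse_complement(substr(mir, 2, 13)))
  expect_identical(p0$n_extended, 0L)
  # outside the 12-mer nothing changed
  expect_identical(substr(p0$sequence, 1, 50), substr(seq, 1, 50))
  expect_identical(substr(p0$sequence, 63, 120), substr(seq, 63, 120))

  # full extension: 12 + (21 - 13) = 20 substituted positions forming the
  # antisense of miRNA nt 2..21
  p1 <- plant_site(seq, mir, 50, extend_prob = 1)
  expect_identical(p1$n_extended, 8L)
  expect_identical(substr(p1$sequence, 43, 62),
                   reverse_complement(substr(mir, 2, 21)))

  # planted sites are recovered at their exact coordinate by the scanner
  mirnas <- make_mirnas("m1", mir)
  tx <- make_transcripts("t1", "G1", "noncoding", p0$sequence)
  hits <- find_sites(mirnas, tx)
  expect_true(any(hits$site_start == 50L))
  expect_identical(hits, naive_find_sites(mirnas, tx))
})

test_that("identical configurations give byte-identical bundles", {
  cfg <- simulation_config(seed = 77)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and the seed matters
  b3 <- simulate_dataset(simulation_config(seed = 78))
  expect_false(identical(b1$transcripts$sequence, b3$transcripts$sequence))
})

test_that("the bundle's ground truth is internally consistent", {
  b <- simulate_dataset(simulation_config(seed = 101))
  tr <- b$truth$sites
  # planted regions agree with the annotation-based classifier
  for (r in seq_len(nrow(tr))) {
    ti <- match(tr$transcript_id[r], b$transcripts$transcript_id)
    expect_identical(classify_region(b$transcripts[ti, ], tr$site_start[r]),
                     tr$region[r])
  }
  # every true planted 12-mer is the antisense of its miRNA's nt 2-13
  none <- tr[tr$class == "NONE", ]
  for (r in seq_len(nrow(none))) {
    mseq <- b$mirnas$sequence[match(none$mirna_id[r], b$mirnas$mirna_id)]
    ti <- match(none$transcript_id[r], b$transcripts$transcript_id)
    expect_identical(substr(b$transcripts$sequence[ti], none$site_start[r] + 1,
                            none$site_start[r] + 12),
                     reverse_complement(substr(mseq, 2, 13)))
  }
  # read counts straddle the QC threshold and some lengths are off-range
  expect_true(any(b$mirnas$read_count <= 1400) &&
                any(b$mirnas$read_count > 1400))
  # seed-sharing and conservation truths are recovered by the detectors
  expect_identical(find_seed_mimics(b$mirnas, b$host_mirnas),
                   b$truth$seed_pairs)
  cons <- find_conserved(b$mirnas, b$multispecies)
  expect_identical(sort(cons$mirna_id[cons$detected]),
                   sort(b$truth$conserved$mirna_id))
  got <- cons$matching_species[match(b$truth$conserved$mirna_id,
                                     cons$mirna_id)]
  expect_identical(got, b$truth$conserved$matching_species)
})

test_that("decoy-only bundles yield no accepted interactions", {
  cfg <- simulation_config(seed = 13,
                           n_planted_sites = c(FIVE_UTR = 0L, CDS = 0L,
                                               THREE_UTR = 0L, NCRNA = 0L),
                           n_decoys = c(SEED_GU = 8L, SEED_ONLY = 8L,
                                        SHUFFLED = 0L))
  b <- simulate_dataset(cfg)
  qc <- filter_mirnas(b$mirnas)
  sites <- find_sites(qc$kept, b$transcripts)
  key <- function(df) paste(df$mirna_id, df$transcript_id, df$site_start)
  # seed-corrupted decoys are invisible to the exact antisense scanner
  expect_false(any(key(b$truth$sites) %in% key(sites)))
})
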