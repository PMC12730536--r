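test_that("read-count and length thresholds follow their stated semantics", {
  m <- make_mirnas(sprintf("m%d", 1:4),
                   c(strrep("A", 21), strrep("C", 19), strrep("G", 26),
                     strrep("U", 25)),
                   read_count = c(1400L, 1401L, 5000L, 2000L))
  qc <- filter_mirnas(m)
  # "more than 1400 reads": exactly 1400 is rejected
  expect_true("m1" %in% qc$rejected$mirna_id)
  expect_identical(qc$rejected$reasons[qc$rejected$mirna_id == "m1"],
                   "LOW_READS")
  # "between 19 and 25": both endpoints admissible
  expect_true(all(c("m2", "m4") %in% qc$kept$mirna_id))
  # 26 nt exceeds the inclusive range
  expect_identical(qc$rejected$reasons[qc$rejected$mirna_id == "m3"],
                   "BAD_LENGTH")
})

test_that("missing read counts and reverse orientation are rejection reasons", {
  m <- make_mirnas(c("a", "b"), c(strrep("A", 21), strrep("C", 21)),
                   read_count = c(NA, 9999L),
                   orientation = c("forward", "reverse"))
  qc <- filter_mirnas(m)
  expect_identical(nrow(qc$kept), 0L)
  expect_identical(qc$rejected$reasons, c("LOW_READS", "BAD_ORIENTATION"))
  # without required read counts, an absent count is not penalized
  qc2 <- filter_mirnas(m, require_read_counts = FALSE)
  expect_identical(qc2$kept$mirna_id, "a")
})

test_that("the fifteen fixture miRNAs pass QC at a 2000-read count", {
  m <- maize_mirna_fixture()
  m$read_count <- 2000L
  qc <- filter_mirnas(m)
  expect_identical(nrow(qc$kept), 15L)
  expect_identical(nrow(qc$rejected), 0L)
})

test_that("filtering partitions its input, is idempotent and monotone", {
  set.seed(9)
  for (r in 1:10) {
    n <- sample(5:40, 1)
    m <- make_mirnas(sprintf("m%03d", seq_len(n)),
                     vapply(sample(15:28, n, replace = TRUE), rand_rna,
                            character(1)),
                     read_count = sample(c(NA, 100L, 1400L, 1500L, 90000L), n,
                                         replace = TRUE),
                     orientation = sample(c("forward", "reverse"), n,
                                          replace = TRUE, prob = c(0.9, 0.1)))
    qc <- filter_mirnas(m)
    expect_identical(nrow(qc$kept) + nrow(qc$rejected), n)
    expect_identical(sort(c(qc$kept$mirna_id, qc$rejected$mirna_id)),
                     sort(m$mirna_id))
    # kept records satisfy every active criterion
    expect_true(all(qc$kept$read_count > 1400L))
    expect_true(all(nchar(qc$kept$sequence) >= 19 &
                      nchar(qc$kept$sequence) <= 25))
    expect_true(all(qc$kept$orientation == "forward"))
    # idempotence on the kept set
    qc2 <- filter_mirnas(qc$kept)
    expect_identical(qc2$kept, qc$kept)
    # raising the read threshold never grows the kept set
    stricter <- filter_mirnas(m, min_reads = 5000L)
    expect_true(all(stricter$kept$mirna_id %in% qc$kept$mirna_id))
  }
})
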