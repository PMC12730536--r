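test_that("a fully complementary toy duplex scores as stacks plus initiation", {
  # 8 pairs -> 7 stacks at -2.0 each, +4.0 initiation: -10.0
  d <- hybridize("ACGUACGU", "ACGUACGU", toy_params())
  expect_identical(d$status, "ok")
  expect_equal(d$mfe, -10.0)
  expect_true(d$seed_perfect)
  expect_true(d$seed_gu_free)
  expect_identical(nrow(d$pairs), 8L)
  b <- brute_force_mfe("ACGUACGU", "ACGUACGU", toy_params())
  expect_equal(b$mfe, -10.0)
})

test_that("unsatisfiable seed constraints give a distinct no-structure result", {
  # no U in the window: the all-A seed cannot pair at all
  d <- hybridize("AAAAAAA", "GGGG", toy_params())
  expect_identical(d$status, "no_structure")
  expect_true(is.na(d$mfe))
  expect_false(passes_criteria(d, mfe_threshold = 0))
})

test_that("an isolated pair costs the initiation energy and never passes", {
  # single-position window: at most one pair, no stacks
  d <- hybridize("AAAAAAA", "U", toy_params(), require_seed_wc = FALSE,
                 forbid_seed_gu = FALSE)
  expect_identical(d$status, "ok")
  expect_equal(d$mfe, 4.0)
  expect_false(passes_criteria(fake_duplex(d$mfe), mfe_threshold = -25))
})

test_that("acceptance thresholds are strict and seed flags are required", {
  expect_false(passes_criteria(fake_duplex(-25.0)))          # "below -25"
  expect_true(passes_criteria(fake_duplex(-25.7)))
  expect_false(passes_criteria(fake_duplex(-40, seed_gu_free = FALSE)))
  expect_false(passes_criteria(fake_duplex(-40, seed_perfect = FALSE)))
  expect_true(passes_criteria(fake_duplex(-3), mfe_threshold = NA))
  expect_false(passes_criteria(fake_duplex(NA_real_, status = "no_structure")))
})

test_that("windows are anchored with room for 3' pairing and clipped at edges", {
  tx <- list(transcript_id = "t", sequence = strrep("A", 200))
  w <- make_window(tx, list(site_start = 30L, site_end = 42L),
                   mirna_length = 22L, flank = 10L)
  expect_identical(c(w$window_start, w$window_end), c(11L, 53L))
  expect_identical(nchar(w$sequence), 42L)
  w0 <- make_window(tx, list(site_start = 0L, site_end = 12L),
                    mirna_length = 22L, flank = 10L)
  expect_identical(w0$window_start, 0L)
  w13 <- make_window(tx, list(site_start = 30L, site_end = 42L),
                     mirna_length = 13L, flank = 0L)
  expect_identical(c(w13$window_start, w13$window_end), c(30L, 43L))
})

test_that("the dynamic program matches exhaustive enumeration on random instances", {
  expect_identical(compare_dp_oracle(200, seed = 301), 0L)
})

test_that("relaxing constraints or widening the window never raises the optimum", {
  set.seed(77)
  for (r in 1:25) {
    mir <- rand_rna(sample(7:10, 1))
    win <- rand_rna(sample(6:12, 1))
    strict <- hybridize(mir, win, require_seed_wc = TRUE, forbid_seed_gu = TRUE)
    loose <- hybridize(mir, win, require_seed_wc = TRUE, forbid_seed_gu = FALSE)
    free <- hybridize(mir, win, require_seed_wc = FALSE, forbid_seed_gu = FALSE)
    if (strict$status == "ok") {
      expect_true(loose$status == "ok" && loose$mfe <= strict$mfe + 1e-9)
    }
    if (loose$status == "ok") {
      expect_true(free$status == "ok" && free$mfe <= loose$mfe + 1e-9)
    }
    wider <- hybridize(mir, paste0(rand_rna(6), win, rand_rna(6)),
                       require_seed_wc = FALSE, forbid_seed_gu = FALSE)
    if (free$status == "ok") {
      expect_true(wider$status == "ok" && wider$mfe <= free$mfe + 1e-9)
    }
  }
})

test_that("brute force refuses instances beyond its enumeration bound", {
  expect_error(brute_force_mfe(rand_rna(11), rand_rna(8)), "limited")
  expect_error(brute_force_mfe(rand_rna(8), rand_rna(13)), "limited")
})

test_that("energy parameters validate, round-trip through files", {
  expect_error(energy_parameters(helix_init = -1))
  bad <- default_energy_parameters()$stack
  bad["CG", "GC"] <- 0.5
  expect_error(energy_parameters(stack = bad), "<= 0")

  p <- energy_parameters(bulge_open = 2.5, max_bulge = 7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_parameters(p, path)
  q <- read_energy_parameters(path)
  expect_equal(q$stack, p$stack)
  expect_equal(q$bulge_open, 2.5)
  expect_identical(q$max_bulge, 7L)
})

test_that("the duplex diagram displays the window 5'->3' over the miRNA 3'->5'", {
  d <- hybridize("ACGUACGU", "ACGUACGU", toy_params())
  lines <- strsplit(d$diagram, "\n")[[1]]
  expect_length(lines, 4L)
  expect_match(lines[1], "^target 5'")
  expect_match(lines[2], "ACGUACGU")
  expect_match(lines[3], "UGCAUGCA")
  expect_match(lines[4], "5'$")
})
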