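# shared fixtures and independent oracles, built in code

PAIRS6 <- c("AU", "CG", "GC", "UA", "GU", "UG")

# uniform toy energy model: every admissible stack -2.0, helix_init +4.0,
# bulge 3.0 + 0.5 * size, internal 4.0 + 0.3 * size
toy_params <- function() {
  energy_parameters(stack = matrix(-2, 6, 6, dimnames = list(PAIRS6, PAIRS6)),
                    helix_init = 4, bulge_open = 3, bulge_ext = 0.5,
                    internal_open = 4, internal_ext = 0.3)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

make_transcripts <- function(ids, genes, biotypes, seqs,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  data.frame(transcript_id = ids, gene_symbol = genes, biotype = biotypes,
             sequence = seqs, cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

make_mirnas <- function(ids, seqs, species = "zma", read_count = NA_integer_,
                        orientation = "forward") {
  data.frame(mirna_id = ids, species = species, sequence = seqs,
             read_count = read_count, orientation = orientation,
             stringsAsFactors = FALSE)
}

# naive O(n*m) sliding-window scan: the independent oracle for find_sites
naive_find_sites <- function(mirnas, transcripts) {
  rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    pat <- reverse_complement(substr(mirnas$sequence[k], 2, 13))
    for (t in seq_len(nrow(transcripts))) {
      s <- transcripts$sequence[t]
      if (nchar(s) < 12L) next
      for (p in seq_len(nchar(s) - 11L)) {
        if (substr(s, p, p + 11L) == pat) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mirnas$mirna_id[k],
            transcript_id = transcripts$transcript_id[t],
            site_start = p - 1L, site_end = p + 11L, site_sequence = pat,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      site_sequence = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$transcript_id, out$site_start, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# a minimal duplex_structure stand-in for threshold-semantics tests
fake_duplex <- function(mfe, seed_perfect = TRUE, seed_gu_free = TRUE,
                        status = "ok") {
  structure(list(pairs = matrix(integer(0), ncol = 2), mfe = mfe,
                 status = status, seed_perfect = seed_perfect,
                 seed_gu_free = seed_gu_free, diagram = ""),
            class = "duplex_structure")
}

# random DP-vs-oracle comparison used by both the unit and acceptance suites;
# returns the number of disagreements
compare_dp_oracle <- function(n_instances, seed) {
  set.seed(seed)
  toy <- toy_params()
  dflt <- default_energy_parameters()
  bad <- 0L
  for (r in seq_len(n_instances)) {
    m <- sample(4:10, 1)
    n <- sample(4:12, 1)
    mir <- rand_rna(m)
    win <- rand_rna(n)
    rw <- sample(c(TRUE, FALSE), 1)
    fg <- sample(c(TRUE, FALSE), 1)
    pars <- if (r %% 2L == 0L) toy else dflt
    h <- hybridize(mir, win, pars, require_seed_wc = rw, forbid_seed_gu = fg)
    b <- brute_force_mfe(mir, win, pars, require_seed_wc = rw,
                         forbid_seed_gu = fg)
    agree <- identical(h$status, b$status) &&
      (h$status != "ok" || isTRUE(all.equal(h$mfe, b$mfe, tolerance = 1e-9)))
    if (agree && h$status == "ok") {
      # the DP's structure must re-score to its own reported energy
      agree <- isTRUE(all.equal(duplex_energy(h$pairs, mir, win, pars), h$mfe,
                                tolerance = 1e-9))
    }
    if (!agree) bad <- bad + 1L
  }
  bad
}
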