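# Local RNG scoping: seeded operations must not disturb the caller's
# random stream, and identical seeds must give identical results.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", saved, envir = globalenv())
  }
  invisible()
}
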