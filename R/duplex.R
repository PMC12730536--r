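# Intermolecular nearest-neighbor duplex minimum-free-energy model.
#
# A duplex between a miRNA (positions 1..m, 5'->3') and a target window
# (positions 1..n, 5'->3') is an ordered list of base pairs (i, j) with i
# strictly increasing and j strictly decreasing (antiparallel, no
# pseudoknots, no intramolecular pairs). Its free energy is
#   helix_init + sum over consecutive pair steps of
#     stacking energy           (both strands advance by one)
#     bulge penalty (affine)    (one strand loops out, size <= max_bulge)
#     internal-loop penalty     (both strands loop out, total size <=
#                                max_internal_loop)
# Unpaired terminal nucleotides cost nothing. Energies are reported at the
# 0.01 kcal/mol resolution of the parameter tables.

PAIR_CODES <- c("AU", "CG", "GC", "UA", "GU", "UG")
WC_CODES <- 1:4
GU_CODES <- 5:6

.base_index <- c(A = 1L, C = 2L, G = 3L, U = 4L)

# 16-entry lookup: (base1, base2) -> pair code 1..6, or 0 if not admissible
.pair_lookup <- local({
  lk <- integer(16)
  for (k in seq_along(PAIR_CODES)) {
    a <- .base_index[[substr(PAIR_CODES[k], 1, 1)]]
    b <- .base_index[[substr(PAIR_CODES[k], 2, 2)]]
    lk[(a - 1L) * 4L + b] <- k
  }
  lk
})

.default_stack <- local({
  m <- matrix(c(
    # AU     CG     GC     UA     GU     UG      (3' pair ->)
    -0.93, -2.24, -2.08, -1.10, -0.55, -1.36,  # AU (5' pair)
    -2.11, -3.26, -2.36, -2.08, -1.41, -2.11,  # CG
    -2.35, -3.42, -3.26, -2.24, -1.53, -2.51,  # GC
    -1.33, -2.35, -2.11, -0.93, -1.00, -1.27,  # UA
    -1.27, -2.51, -2.11, -1.36, -0.50,  1.29,  # GU
    -1.00, -1.53, -1.41, -0.55,  0.30, -0.50   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(PAIR_CODES, PAIR_CODES))
  m
})

#' Energy parameters for the duplex model
#'
#' Bundles a 6x6 stacking table over the admissible pairs
#' (`AU, CG, GC, UA, GU, UG`; row = pair closer to the miRNA 5' end),
#' affine bulge and internal-loop penalties, a helix-initiation term and
#' loop-size caps. The default stacking table holds RNA nearest-neighbor
#' stacking free energies at 37 C in the style of the Turner rules
#' (Watson-Crick and wobble stacks); penalties and initiation are single
#' documented defaults and everything is overridable here or via
#' [read_energy_parameters()].
#'
#' @param stack 6x6 numeric matrix with dimnames `PAIR_CODES` x
#'   `PAIR_CODES`, kcal/mol; Watson-Crick/Watson-Crick entries must be
#'   <= 0.
#' @param helix_init Duplex initiation cost, kcal/mol (>= 0).
#' @param bulge_open,bulge_ext Affine bulge penalty: `bulge_open +
#'   bulge_ext * size`, kcal/mol.
#' @param internal_open,internal_ext Affine internal-loop penalty on the
#'   total loop size (both strands summed).
#' @param max_bulge,max_internal_loop Maximum admissible loop sizes.
#' @return An object of class `energy_parameters`.
#' @export
energy_parameters <- function(stack = .default_stack,
                              helix_init = 4.09,
                              bulge_open = 3.3, bulge_ext = 0.5,
                              internal_open = 2.9, internal_ext = 0.4,
                              max_bulge = 15L, max_internal_loop = 15L) {
  stopifnot(is.matrix(stack), all(dim(stack) == c(6L, 6L)))
  if (!identical(rownames(stack), PAIR_CODES) ||
      !identical(colnames(stack), PAIR_CODES)) {
    stop("stack table must have dimnames ", paste(PAIR_CODES, collapse = ","))
  }
  if (any(stack[WC_CODES, WC_CODES] > 0)) {
    stop("Watson-Crick/Watson-Crick stacking energies must be <= 0")
  }
  stopifnot(helix_init >= 0, bulge_open >= 0, bulge_ext >= 0,
            internal_open >= 0, internal_ext >= 0,
            max_bulge >= 1L, max_internal_loop >= 1L)
  structure(list(stack = stack, helix_init = helix_init,
                 bulge_open = bulge_open, bulge_ext = bulge_ext,
                 internal_open = internal_open, internal_ext = internal_ext,
                 max_bulge = as.integer(max_bulge),
                 max_internal_loop = as.integer(max_internal_loop)),
            class = "energy_parameters")
}

#' @rdname energy_parameters
#' @export
default_energy_parameters <- function() energy_parameters()

#' Read / write an energy-parameter file
#'
#' Tab-separated with a header and columns `record`, `a`, `b`, `value`:
#' `stack` records give `a` = 5' pair, `b` = 3' pair and the stacking
#' energy; `scalar` records give the parameter name in `a` (`helix_init`,
#' `bulge_open`, `bulge_ext`, `internal_open`, `internal_ext`,
#' `max_bulge`, `max_internal_loop`) with `b` empty.
#'
#' @param path File path.
#' @param params An `energy_parameters` object (writer).
#' @return An `energy_parameters` object (reader); `path` invisibly
#'   (writer).
#' @export
read_energy_parameters <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("record", "a", "b", "value") %in% names(df)))
  stk <- .default_stack
  sc <- list()
  for (r in seq_len(nrow(df))) {
    if (df$record[r] == "stack") {
      if (!(df$a[r] %in% PAIR_CODES) || !(df$b[r] %in% PAIR_CODES)) {
        stop(sprintf("bad stack pair codes at row %d: %s/%s", r, df$a[r], df$b[r]))
      }
      stk[df$a[r], df$b[r]] <- df$value[r]
    } else if (df$record[r] == "scalar") {
      sc[[df$a[r]]] <- df$value[r]
    } else {
      stop(sprintf("unknown record type '%s' at row %d", df$record[r], r))
    }
  }
  args <- c(list(stack = stk), sc)
  do.call(energy_parameters, args)
}

#' @rdname read_energy_parameters
#' @export
write_energy_parameters <- function(params, path) {
  stopifnot(inherits(params, "energy_parameters"))
  grid <- expand.grid(a = PAIR_CODES, b = PAIR_CODES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stack_df <- data.frame(record = "stack", a = grid$a, b = grid$b,
                         value = params$stack[cbind(grid$a, grid$b)],
                         stringsAsFactors = FALSE)
  scalars <- c("helix_init", "bulge_open", "bulge_ext", "internal_open",
               "internal_ext", "max_bulge", "max_internal_loop")
  scalar_df <- data.frame(record = "scalar", a = scalars, b = "",
                          value = unlist(params[scalars]),
                          stringsAsFactors = FALSE)
  utils::write.table(rbind(stack_df, scalar_df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# encode a sequence as base indices 1..4
.encode <- function(sequence) {
  unname(.base_index[strsplit(sequence, "", fixed = TRUE)[[1]]])
}

# pair-code matrix: ptype[i, j] in 0..6 for miRNA base i vs window base j
.pair_type_matrix <- function(x, y) {
  matrix(.pair_lookup[(rep(x, times = length(y)) - 1L) * 4L +
                        rep(y, each = length(x))],
         nrow = length(x), ncol = length(y))
}

# validity of each cell under the active seed constraints
.valid_matrix <- function(ptype, require_seed_wc, forbid_seed_gu) {
  valid <- ptype > 0L
  m <- nrow(ptype)
  seed_rows <- intersect(2:7, seq_len(m))
  if (require_seed_wc && length(seed_rows) > 0L) {
    valid[seed_rows, ] <- valid[seed_rows, , drop = FALSE] &
      matrix(ptype[seed_rows, , drop = FALSE] %in% WC_CODES,
             nrow = length(seed_rows))
  }
  if (forbid_seed_gu && length(seed_rows) > 0L) {
    valid[seed_rows, ] <- valid[seed_rows, , drop = FALSE] &
      !matrix(ptype[seed_rows, , drop = FALSE] %in% GU_CODES,
              nrow = length(seed_rows))
  }
  valid
}

# largest successor miRNA position reachable from position i without
# leaving a seed position (2..7) unpaired; Inf when unconstrained
.row_cap <- function(i, require_seed_wc, m) {
  if (!require_seed_wc) return(m)
  if (i < 2L) return(2L)
  if (i < 7L) return(i + 1L)
  m
}

.step_cost <- function(di, dj, p1, p2, params) {
  if (di == 0L && dj == 0L) return(params$stack[p1, p2])
  if (di == 0L || dj == 0L) {
    size <- di + dj
    if (size > params$max_bulge) return(Inf)
    return(params$bulge_open + params$bulge_ext * size)
  }
  size <- di + dj
  if (size > params$max_internal_loop) return(Inf)
  params$internal_open + params$internal_ext * size
}

# energy of an explicit pair list (k x 2 matrix: miRNA pos, window pos),
# shared model definition used by both search strategies and by tests
.energy_of_pairs <- function(pairs, ptype, params) {
  pairs <- unname(pairs)
  k <- nrow(pairs)
  if (k == 0L) return(Inf)
  codes <- ptype[pairs]
  if (any(codes == 0L)) stop("inadmissible base pair in structure")
  if (k > 1L) {
    if (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) >= 0L)) {
      stop("pairs must be strictly increasing in miRNA position and decreasing in target position")
    }
  }
  e <- params$helix_init
  if (k > 1L) {
    for (s in seq_len(k - 1L)) {
      di <- pairs[s + 1L, 1] - pairs[s, 1] - 1L
      dj <- pairs[s, 2] - pairs[s + 1L, 2] - 1L
      st <- .step_cost(di, dj, codes[s], codes[s + 1L], params)
      if (!is.finite(st)) stop("loop size exceeds the configured maximum")
      e <- e + st
    }
  }
  e
}

#' Recompute the free energy of an explicit duplex pair list
#'
#' Useful for validating structures and for cross-checking search results;
#' applies the same energy decomposition as [hybridize()].
#'
#' @param pairs Integer matrix with two columns (miRNA position, 1-based;
#'   window position, 1-based), ordered by miRNA position.
#' @param mirna,window RNA sequences.
#' @param params An [energy_parameters()] object.
#' @return Free energy in kcal/mol (rounded to 0.01).
#' @export
duplex_energy <- function(pairs, mirna, window,
                          params = default_energy_parameters()) {
  x <- .encode(normalize_sequence(mirna))
  y <- .encode(normalize_sequence(window))
  ptype <- .pair_type_matrix(x, y)
  round(.energy_of_pairs(pairs, ptype, params), 2)
}

.seed_flags <- function(pairs, ptype, m) {
  seed_pos <- intersect(2:7, seq_len(m))
  in_seed <- pairs[, 1] %in% seed_pos
  codes <- ptype[pairs]
  seed_codes <- codes[in_seed]
  seed_perfect <- m >= 7L && sum(in_seed) == 6L && all(seed_codes %in% WC_CODES)
  seed_gu_free <- !any(seed_codes %in% GU_CODES)
  list(seed_perfect = seed_perfect, seed_gu_free = seed_gu_free)
}

.no_structure <- function() {
  structure(list(pairs = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("mirna_pos", "window_pos"))),
                 mfe = NA_real_, status = "no_structure",
                 seed_perfect = FALSE, seed_gu_free = FALSE,
                 diagram = ""),
            class = "duplex_structure")
}

.make_structure <- function(pairs, mfe, mirna, window, ptype) {
  colnames(pairs) <- c("mirna_pos", "window_pos")
  fl <- .seed_flags(pairs, ptype, nchar(mirna))
  structure(list(pairs = pairs, mfe = round(mfe, 2), status = "ok",
                 seed_perfect = fl$seed_perfect,
                 seed_gu_free = fl$seed_gu_free,
                 diagram = .render_diagram(pairs, mirna, window)),
            class = "duplex_structure")
}

#' Minimum-free-energy hybridization of a miRNA with a target window
#'
#' Finds the minimum-energy antiparallel intermolecular duplex between the
#' miRNA and the window under the nearest-neighbor model described in
#' [energy_parameters()], by dynamic programming over all non-crossing
#' pair lists with at least one pair. Two optional constraints implement
#' the seed criteria of the prediction pipeline: with `require_seed_wc`
#' every miRNA position 2-7 must be paired by a Watson-Crick pair; with
#' `forbid_seed_gu` no G:U wobble is allowed at positions 2-7. If no
#' admissible structure exists under the constraints, a distinct
#' "no structure" result is returned (never an energy of zero).
#'
#' Ties between co-optimal structures are broken deterministically toward
#' the lexicographically smallest pair list (5'-proximal miRNA position
#' first, then 5'-proximal window position).
#'
#' @param mirna Mature miRNA sequence (RNA or DNA alphabet; normalized).
#' @param window Target window sequence, 5' to 3' in transcript
#'   orientation.
#' @param params An [energy_parameters()] object.
#' @param require_seed_wc,forbid_seed_gu Logical constraint switches
#'   (both default `TRUE`, the standard pipeline setting).
#' @return An object of class `duplex_structure` with elements `pairs`
#'   (matrix of miRNA/window positions, 1-based), `mfe` (kcal/mol),
#'   `status` (`"ok"` or `"no_structure"`), `seed_perfect`,
#'   `seed_gu_free` and a 4-line text `diagram`.
#' @export
hybridize <- function(mirna, window, params = default_energy_parameters(),
                      require_seed_wc = TRUE, forbid_seed_gu = TRUE) {
  mirna <- normalize_sequence(mirna)
  window <- normalize_sequence(window)
  m <- nchar(mirna)
  n <- nchar(window)
  if (require_seed_wc && m < 7L) return(.no_structure())
  x <- .encode(mirna)
  y <- .encode(window)
  ptype <- .pair_type_matrix(x, y)
  valid <- .valid_matrix(ptype, require_seed_wc, forbid_seed_gu)
  if (!any(valid)) return(.no_structure())

  gapcap <- max(params$max_bulge, params$max_internal_loop)
  # S[i, j]: best suffix energy (steps only) of a structure whose
  # 5'-most remaining pair is (i, j); Inf when infeasible
  S <- matrix(Inf, nrow = m, ncol = n)
  term_ok <- if (require_seed_wc) seq_len(m) >= 7L else rep(TRUE, m)

  for (i in m:1) {
    best <- rep(Inf, n)
    if (term_ok[i]) best[] <- 0
    cap <- .row_cap(i, require_seed_wc, m)
    i2_max <- min(m, cap, i + 1L + gapcap)
    if (i + 1L <= i2_max) {
      for (i2 in (i + 1L):i2_max) {
        di <- i2 - i - 1L
        row2 <- S[i2, ]
        if (all(!is.finite(row2))) next
        if (di == 0L) {
          # contiguous stack (dj = 0)
          if (n >= 2L) {
            p1 <- ptype[i, 2:n]
            p2 <- ptype[i2, 1:(n - 1L)]
            sv <- rep(Inf, n - 1L)
            okp <- p1 > 0L & p2 > 0L
            sv[okp] <- params$stack[cbind(p1[okp], p2[okp])]
            best <- pmin(best, c(Inf, sv + row2[1:(n - 1L)]))
          }
          # target-side bulges (dj >= 1)
          dj_max <- min(params$max_bulge, n - 2L)
          if (dj_max >= 1L) {
            for (dj in 1:dj_max) {
              pen <- params$bulge_open + params$bulge_ext * dj
              best <- pmin(best, c(rep(Inf, 1L + dj),
                                   pen + row2[1:(n - 1L - dj)]))
            }
          }
        } else {
          # miRNA-side bulge (dj = 0)
          if (di <= params$max_bulge && n >= 2L) {
            pen <- params$bulge_open + params$bulge_ext * di
            best <- pmin(best, c(Inf, pen + row2[1:(n - 1L)]))
          }
          # internal loops (dj >= 1, total size <= max_internal_loop)
          dj_max <- min(params$max_internal_loop - di, n - 2L)
          if (dj_max >= 1L) {
            for (dj in 1:dj_max) {
              pen <- params$internal_open + params$internal_ext * (di + dj)
              best <- pmin(best, c(rep(Inf, 1L + dj),
                                   pen + row2[1:(n - 1L - dj)]))
            }
          }
        }
      }
    }
    best[!valid[i, ]] <- Inf
    S[i, ] <- best
  }

  start_rows <- if (require_seed_wc) seq_len(min(2L, m)) else seq_len(m)
  sub <- S[start_rows, , drop = FALSE]
  if (!any(is.finite(sub))) return(.no_structure())
  raw_mfe <- params$helix_init + min(sub)
  tol <- 1e-9

  # forward traceback, lexicographically smallest co-optimal pair list
  start <- NULL
  for (i in start_rows) {
    hit <- which(S[i, ] <= min(sub) + tol)
    if (length(hit) > 0L) { start <- c(i, hit[1L]); break }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- start[1L]; j <- start[2L]
  repeat {
    pairs <- rbind(pairs, c(i, j))
    if (term_ok[i] && S[i, j] >= -tol) break
    found <- FALSE
    cap <- .row_cap(i, require_seed_wc, m)
    i2_hi <- min(m, cap, i + 1L + gapcap)
    if (i + 1L > i2_hi) stop("internal error: duplex traceback failed")
    for (i2 in (i + 1L):i2_hi) {
      if (found) break
      for (j2 in seq_len(j - 1L)) {
        if (!valid[i2, j2] || !is.finite(S[i2, j2])) next
        st <- .step_cost(i2 - i - 1L, j - j2 - 1L, ptype[i, j], ptype[i2, j2],
                         params)
        if (is.finite(st) && st + S[i2, j2] <= S[i, j] + tol) {
          i <- i2; j <- j2; found <- TRUE; break
        }
      }
    }
    if (!found) stop("internal error: duplex traceback failed")
  }
  .make_structure(pairs, raw_mfe, mirna, window, ptype)
}

#' Exhaustive-enumeration oracle for the duplex minimum free energy
#'
#' Enumerates every antiparallel non-crossing pair list (at least one
#' pair) within hard size bounds and returns the exact optimum under the
#' same contract as [hybridize()]. Intended as an independent test oracle;
#' the search is a direct enumeration and shares no recurrence with the
#' dynamic program.
#'
#' @inheritParams hybridize
#' @return A `duplex_structure`, as for [hybridize()].
#' @export
brute_force_mfe <- function(mirna, window, params = default_energy_parameters(),
                            require_seed_wc = TRUE, forbid_seed_gu = TRUE) {
  mirna <- normalize_sequence(mirna)
  window <- normalize_sequence(window)
  m <- nchar(mirna)
  n <- nchar(window)
  if (m > 10L || n > 12L) {
    stop("brute_force_mfe is limited to miRNA <= 10 nt and window <= 12 nt")
  }
  if (require_seed_wc && m < 7L) return(.no_structure())
  x <- .encode(mirna)
  y <- .encode(window)
  ptype <- .pair_type_matrix(x, y)
  valid <- .valid_matrix(ptype, require_seed_wc, forbid_seed_gu)
  term_ok <- if (require_seed_wc) seq_len(m) >= 7L else rep(TRUE, m)
  tol <- 1e-9
  best_e <- Inf
  best_pairs <- NULL

  rec <- function(pairs, i, j, e) {
    if (term_ok[i] && e < best_e - tol) {
      best_e <<- e
      best_pairs <<- pairs
    }
    cap <- .row_cap(i, require_seed_wc, m)
    if (i + 1L > min(m, cap)) return(invisible())
    for (i2 in (i + 1L):min(m, cap)) {
      for (j2 in seq_len(j - 1L)) {
        if (!valid[i2, j2]) next
        st <- .step_cost(i2 - i - 1L, j - j2 - 1L, ptype[i, j], ptype[i2, j2],
                         params)
        if (!is.finite(st)) next
        rec(rbind(pairs, c(i2, j2)), i2, j2, e + st)
      }
    }
    invisible()
  }

  start_rows <- if (require_seed_wc) seq_len(min(2L, m)) else seq_len(m)
  for (i1 in start_rows) {
    for (j1 in seq_len(n)) {
      if (!valid[i1, j1]) next
      rec(matrix(c(i1, j1), ncol = 2), i1, j1, params$helix_init)
    }
  }
  if (!is.finite(best_e)) return(.no_structure())
  .make_structure(best_pairs, best_e, mirna, window, ptype)
}

#' Does a duplex satisfy the interaction-selection criteria?
#'
#' The standard criteria are: perfect Watson-Crick pairing of the seed
#' (miRNA nucleotides 2-7), no G:U wobble in the seed, and a minimum free
#' energy strictly below the threshold ("below -25 kcal/mol", so exactly
#' -25.0 is rejected). The threshold can be disabled with `NA` (used for
#' the seed-mimicry re-scoring stage).
#'
#' @param duplex A `duplex_structure`.
#' @param mfe_threshold Threshold in kcal/mol (strict), or `NA`/`NULL`
#'   to disable.
#' @return `TRUE` or `FALSE`.
#' @export
passes_criteria <- function(duplex, mfe_threshold = -25.0) {
  stopifnot(inherits(duplex, "duplex_structure"))
  if (duplex$status != "ok") return(FALSE)
  if (!duplex$seed_perfect || !duplex$seed_gu_free) return(FALSE)
  if (is.null(mfe_threshold) || is.na(mfe_threshold)) return(TRUE)
  duplex$mfe < mfe_threshold
}

#' Target window around a candidate seed-match site
#'
#' Extracts the transcript window the hybridization stage scores: the
#' 12-nt anchor plus room upstream (in transcript coordinates) for pairing
#' of miRNA nucleotides 14..L, one position downstream for miRNA
#' nucleotide 1, and `flank` nucleotides of slack on each side for bulges,
#' clipped to the transcript:
#' `[site_start - (mirna_length - 13) - flank, site_end + 1 + flank)`.
#'
#' @param transcript A one-row data frame (or list) with `transcript_id`
#'   and `sequence`.
#' @param seed_match A one-row data frame (or list) with `site_start` and
#'   `site_end` (0-based half-open).
#' @param mirna_length Length of the miRNA to be hybridized.
#' @param flank Extra slack per side, nucleotides (default 10).
#' @return A list with `transcript_id`, `window_start`, `window_end`
#'   (0-based half-open) and `sequence`.
#' @export
make_window <- function(transcript, seed_match, mirna_length, flank = 10L) {
  len <- nchar(transcript$sequence)
  stopifnot(seed_match$site_start >= 0L, seed_match$site_end <= len)
  ws <- max(0L, as.integer(seed_match$site_start - (mirna_length - 13L) - flank))
  we <- min(len, as.integer(seed_match$site_end + 1L + flank))
  list(transcript_id = transcript$transcript_id,
       window_start = ws, window_end = we,
       sequence = substr(transcript$sequence, ws + 1L, we))
}

# 4-line text diagram in the style of hybridization tools: target 5'->3'
# on top (unpaired above, paired below), miRNA 3'->5' underneath
.render_diagram <- function(pairs, mirna, window) {
  if (nrow(pairs) == 0L) return("")
  xs <- strsplit(mirna, "", fixed = TRUE)[[1]]
  ys <- strsplit(window, "", fixed = TRUE)[[1]]
  # order pairs by window position ascending (miRNA position descending)
  ord <- order(pairs[, 2])
  p <- pairs[ord, , drop = FALSE]
  l1 <- l2 <- l3 <- l4 <- character(0)
  emit <- function(t_un, t_pr, m_pr, m_un) {
    l1 <<- c(l1, t_un); l2 <<- c(l2, t_pr); l3 <<- c(l3, m_pr); l4 <<- c(l4, m_un)
  }
  pad_cols <- function(t_run, m_run) {
    w <- max(length(t_run), length(m_run))
    t_run <- c(t_run, rep(" ", w - length(t_run)))
    m_run <- c(m_run, rep(" ", w - length(m_run)))
    for (k in seq_len(w)) emit(t_run[k], " ", " ", m_run[k])
  }
  # leading unpaired context
  lead_t <- if (p[1, 2] > 1L) ys[seq_len(p[1, 2] - 1L)] else character(0)
  lead_m <- if (p[1, 1] < length(xs)) rev(xs[(p[1, 1] + 1L):length(xs)]) else character(0)
  pad_cols(lead_t, lead_m)
  emit(" ", ys[p[1, 2]], xs[p[1, 1]], " ")
  if (nrow(p) > 1L) {
    for (s in 2:nrow(p)) {
      gap_t <- if (p[s, 2] - p[s - 1, 2] > 1L) ys[(p[s - 1, 2] + 1L):(p[s, 2] - 1L)] else character(0)
      gap_m <- if (p[s - 1, 1] - p[s, 1] > 1L) rev(xs[(p[s, 1] + 1L):(p[s - 1, 1] - 1L)]) else character(0)
      pad_cols(gap_t, gap_m)
      emit(" ", ys[p[s, 2]], xs[p[s, 1]], " ")
    }
  }
  last <- nrow(p)
  trail_t <- if (p[last, 2] < length(ys)) ys[(p[last, 2] + 1L):length(ys)] else character(0)
  trail_m <- if (p[last, 1] > 1L) rev(xs[seq_len(p[last, 1] - 1L)]) else character(0)
  pad_cols(trail_t, trail_m)
  paste(c(paste0("target 5' ", paste(l1, collapse = ""), " 3'"),
          paste0("          ", paste(l2, collapse = "")),
          paste0("          ", paste(l3, collapse = "")),
          paste0("miRNA  3' ", paste(l4, collapse = ""), " 5'")),
        collapse = "\n")
}

#' @export
print.duplex_structure <- function(x, ...) {
  if (x$status != "ok") {
    cat("duplex: no admissible structure\n")
    return(invisible(x))
  }
  cat(sprintf("duplex: mfe %.2f kcal/mol, %d pairs, seed_perfect=%s, seed_gu_free=%s\n",
              x$mfe, nrow(x$pairs), x$seed_perfect, x$seed_gu_free))
  cat(x$diagram, "\n")
  invisible(x)
}
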