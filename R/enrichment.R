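#' Upper-tail hypergeometric probability for over-representation
#'
#' Probability of observing `k` or more query genes inside a set of size
#' `K`, when `n` query genes are drawn without replacement from a
#' background of `N`:
#' `sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`, accumulated in log
#' space for numerical stability.
#'
#' @param k Observed overlap (vectorized).
#' @param K Gene-set size.
#' @param n Query-list size.
#' @param N Background size.
#' @return Upper-tail probability(ies) in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(K <= N, n <= N, all(k >= 0), all(k <= pmin(K, n)))
  vapply(k, function(kk) {
    if (kk == 0) return(1.0)
    j <- kk:min(K, n)
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    mx <- max(lp)
    min(1, exp(mx + log(sum(exp(lp - mx)))))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order
#' (invariant under permutation of the input).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR q-values) in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against gene sets
#'
#' One-sided hypergeometric test per set with Benjamini-Hochberg FDR
#' across the collection; this is the standard offline equivalent of
#' web-based enrichment services' adjusted p-value (proprietary combined
#' rankings are not reproduced). Query genes absent from the background
#' are dropped (their count is reported, never silently discarded), and
#' set members outside the background are ignored in the overlap counts.
#'
#' @param query_genes Character vector of gene symbols.
#' @param gene_sets Named list of character vectors (term -> members),
#'   e.g. from [read_gmt()].
#' @param background Character vector: the gene universe.
#' @param top_k Number of rows in the significant-term report
#'   (default 10).
#' @param fdr_cut FDR threshold for the report (default 0.05).
#' @return An object of class `enrichment_result`: list with `table`
#'   (all sets, columns `term`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `overlap_genes`, sorted by `(fdr, p_value, term)`), `report` (the
#'   first `top_k` rows with `fdr < fdr_cut`) and `n_query_dropped`.
#' @export
enrich <- function(query_genes, gene_sets, background, top_k = 10L,
                   fdr_cut = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query0 <- unique(query_genes)
  query <- intersect(query0, background)
  n_dropped <- length(query0) - length(query)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), background)
    overlap <- intersect(members, query)
    K <- length(members)
    k <- length(overlap)
    p <- if (K == 0L) 1.0 else hypergeom_upper_tail(k, K, n, N)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE)
  }
  tab$fdr <- bh_adjust(tab$p_value)
  tab <- tab[order(tab$fdr, tab$p_value, tab$term),
             c("term", "k", "K", "n", "N", "p_value", "fdr", "overlap_genes")]
  rownames(tab) <- NULL
  report <- tab[tab$fdr < fdr_cut, , drop = FALSE]
  report <- utils::head(report, top_k)
  rownames(report) <- NULL
  structure(list(table = tab, report = report, n_query_dropped = n_dropped),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d sets tested, %d significant reported, %d query genes outside background\n",
              nrow(x$table), nrow(x$report), x$n_query_dropped))
  if (nrow(x$report) > 0L) {
    print(x$report[, c("term", "k", "K", "p_value", "fdr")])
  }
  invisible(x)
}

#' Null calibration of the over-representation p-value
#'
#' Simulates the null hypothesis -- a query list drawn uniformly at random
#' from the background -- and measures how often a single gene set attains
#' `p < alpha`. The overlap of a uniformly drawn query with a fixed set is
#' exactly hypergeometric, so each draw is simulated directly as the
#' overlap count and scored with [hypergeom_upper_tail()]. For a
#' well-calibrated (if conservative, due to discreteness) test the
#' empirical rate approaches `alpha` from below as the counts grow.
#'
#' @param n_draws Number of simulated null queries.
#' @param set_size,query_size,background_size Hypergeometric dimensions.
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed for the draws.
#' @return A list with `rate` (empirical `P(p < alpha)`), `n_draws` and
#'   `alpha`.
#' @export
null_pvalue_calibration <- function(n_draws, set_size, query_size,
                                    background_size, alpha = 0.05,
                                    seed = 1L) {
  stopifnot(set_size <= background_size, query_size <= background_size)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  k <- stats::rhyper(n_draws, set_size, background_size - set_size, query_size)
  uk <- sort(unique(k))
  p_by_k <- hypergeom_upper_tail(uk, set_size, query_size, background_size)
  p <- p_by_k[match(k, uk)]
  list(rate = mean(p < alpha), n_draws = n_draws, alpha = alpha)
}
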