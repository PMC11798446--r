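#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (term, description, member genes per
#'   line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query set overlaps it more
#' than expected by chance: with a universe of N genes of which K belong to
#' the term and a query of n genes with k in the term, the p-value is the
#' upper hypergeometric tail `P(X >= k)`. BH adjustment is applied across
#' the terms of the collection; significance is flagged on the raw p-value
#' (adjusted values are reported alongside).
#'
#' @param query Gene set (character vector or tibble).
#' @param collection Named list of term gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene symbols; query genes outside it are
#'   dropped with a warning. Terms are clipped to the universe.
#' @param alpha Raw-p significance cutoff, default 0.05.
#' @return Tibble sorted by p: `term`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   `significant`.
#' @export
#' @examples
#' hypergeometric_ora(c("A", "B", "C", "D"),
#'                    list(t1 = c("A", "B", "C", "D", "E")),
#'                    universe = LETTERS[1:10])
hypergeometric_ora <- function(query, collection, universe, alpha = 0.05) {
  universe <- normalize_symbols(universe)
  if (length(universe) == 0) stopf("empty universe")
  q <- as_gene_tbl(query)$gene
  outside <- setdiff(q, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    q <- intersect(q, universe)
  }
  N <- length(universe)
  n <- length(q)
  rows <- purrr::imap_dfr(collection, function(members, term) {
    members <- intersect(normalize_symbols(members), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(q, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  if (nrow(rows) == 0) return(rows)
  rows %>%
    mutate(adj_p = bh_adjust(.data$p),
           significant = .data$p < alpha) %>%
    arrange(.data$p, .data$term)
}
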