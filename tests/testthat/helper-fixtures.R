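# Shared fixtures and independent oracles used across test files.

# A small but fully featured synthetic study configuration: fast enough for
# repeated use, large enough that collapsing, blanking and set algebra all
# have work to do.
small_config <- function(seed = 1, samples_per_group = 10, ...) {
  synth_config(universe_size = 60, shared_core_size = 40,
               samples_per_group = samples_per_group, seed = seed, ...)
}

# One-gene expression dataset with explicit values.
one_gene_dataset <- function(values, groups, gene = "GX", name = "fix") {
  m <- matrix(values, nrow = 1,
              dimnames = list(gene, sprintf("s%02d", seq_along(values))))
  expression_dataset(m, groups, name = name)
}

# Brute-force maximal-clique-centrality oracle: enumerate every vertex
# subset, keep cliques that are maximal, and sum (|C| - 1)! per member.
# Independent of igraph's clique enumeration; usable for n <= 12.
mcc_bruteforce <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 12)
  score <- setNames(numeric(n), rownames(adj))
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    pairs <- utils::combn(members, 2)
    if (!all(adj[t(pairs)] == 1)) next
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(v) all(adj[v, members] == 1),
                           logical(1)))
    if (maximal) {
      score[members] <- score[members] + factorial(length(members) - 1)
    }
  }
  score
}

# Random simple graph as a 0/1 adjacency matrix with named vertices.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n, dimnames = list(paste0("v", seq_len(n)),
                                          paste0("v", seq_len(n))))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

graph_from_adjacency_named <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Edge tibble of the complete graph on the given vertex names, confidence 1.
complete_graph_edges <- function(nodes, confidence = 1) {
  pr <- t(utils::combn(nodes, 2))
  tibble::tibble(gene_a = pr[, 1], gene_b = pr[, 2], confidence = confidence)
}
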