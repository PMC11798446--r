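#' Build a confidence-filtered PPI graph
#'
#' Edges with confidence at or above the threshold are retained (the cutoff
#' is inclusive). Confidences on the 0-1000 integer scale (any value above
#' 1) are rescaled by 1/1000 first. Self-loops are dropped; duplicate pairs
#' keep their maximum confidence. Nodes appear only through surviving edges,
#' so there are no isolated vertices.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `confidence`.
#' @param confidence_threshold Minimum confidence, default 0.70.
#' @return An undirected simple [igraph::graph] with edge attribute
#'   `confidence`.
#' @export
build_ppi_graph <- function(edges, confidence_threshold = 0.70) {
  edges <- as_tibble(edges)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% names(edges))) {
    stopf("edge table must have columns %s", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(edges$confidence) | !nzchar(edges$gene_a) |
                 !nzchar(edges$gene_b))
  if (length(bad)) stopf("malformed edge row(s): %s",
                         paste(head(bad, 5), collapse = ", "))
  conf <- edges$confidence
  if (any(conf > 1)) conf <- conf / 1000
  if (any(conf < 0 | conf > 1)) stopf("confidences outside [0, 1] after rescaling")
  a <- toupper(trimws(edges$gene_a))
  b <- toupper(trimws(edges$gene_b))
  lo <- pmin(a, b); hi <- pmax(a, b)
  kept <- tibble(a = lo, b = hi, confidence = conf) %>%
    filter(.data$a != .data$b, .data$confidence >= confidence_threshold) %>%
    group_by(.data$a, .data$b) %>%
    summarise(confidence = max(.data$confidence), .groups = "drop")
  g <- igraph::graph_from_data_frame(kept, directed = FALSE)
  igraph::E(g)$confidence <- kept$confidence
  g
}

#' Maximal clique centrality (MCC)
#'
#' MCC of a node v is the sum, over all maximal cliques C containing v, of
#' `(|C| - 1)!`. On a triangle-free graph this reduces to the node degree.
#' Maximal cliques are enumerated with the pivoted Bron-Kerbosch algorithm.
#'
#' @param g An [igraph::graph].
#' @param clique_budget Abort (with an error, never a silent truncation)
#'   when the graph holds more maximal cliques than this.
#' @return Tibble `gene`, `mcc`, `degree`, sorted by `mcc` descending.
#' @export
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- LETTERS[1:4]
#' mcc_scores(g) # every node (4-1)! = 6
mcc_scores <- function(g, clique_budget = 1e6) {
  n_cl <- igraph::count_max_cliques(g, min = 2)
  if (n_cl > clique_budget) {
    stopf("graph has %d maximal cliques, over the budget of %g; raise clique_budget to proceed",
          n_cl, clique_budget)
  }
  cliques <- igraph::max_cliques(g, min = 2)
  score <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (cl in cliques) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  tibble(gene = names(score), mcc = as.numeric(score),
         degree = as.numeric(igraph::degree(g))) %>%
    arrange(desc(.data$mcc), desc(.data$degree), .data$gene)
}

#' Top-k hub genes by MCC
#'
#' Ties at the boundary are broken by degree (descending), then symbol
#' (ascending).
#'
#' @param scores Tibble from [mcc_scores()].
#' @param k Number of hubs, default 20.
#' @return Tibble `gene`, `mcc`, `degree`, `rank`.
#' @export
top_k_hubs <- function(scores, k = 20) {
  scores <- arrange(scores, desc(.data$mcc), desc(.data$degree), .data$gene)
  if (nrow(scores) < k) {
    warnf("only %d scored nodes available (requested %d hubs)",
          nrow(scores), k)
  }
  head(scores, k) %>% mutate(rank = row_number())
}

#' MCODE parameters
#'
#' @param degree_cutoff Minimum degree for a node to receive weight.
#' @param node_score_cutoff Expansion tolerance: a neighbor joins a complex
#'   when its weight is at least `(1 - node_score_cutoff)` times the seed's.
#' @param k_core Minimum core level required of a vertex neighborhood.
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @param haircut Remove degree-1 vertices from each finished complex.
#' @param fluff Unused placeholder (off, the common default).
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE,
                         fluff = FALSE) {
  stopifnot(degree_cutoff > 0, k_core > 0,
            node_score_cutoff > 0, node_score_cutoff < 1)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 max_depth = max_depth, haircut = haircut, fluff = fluff),
            class = "mcode_params")
}

undirected_density <- function(n, e) if (n < 2) 0 else 2 * e / (n * (n - 1))

#' MCODE vertex weighting
#'
#' A node with degree below `degree_cutoff` weighs 0. Otherwise the highest
#' k-core of the node's closed neighborhood is found; if its core level is
#' below `k_core` the weight is 0, else the weight is the core level times
#' the (undirected) density of that core.
#'
#' @param g An [igraph::graph].
#' @param params An [mcode_params()].
#' @return Tibble `gene`, `weight`.
#' @export
#' @examples
#' g <- igraph::make_full_graph(7)
#' igraph::V(g)$name <- paste0("g", 1:7)
#' mcode_vertex_weights(g) # every vertex: core 6, density 1 -> weight 6
mcode_vertex_weights <- function(g, params = mcode_params()) {
  deg <- igraph::degree(g)
  w <- vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < params$degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k_max <- max(core)
    if (k_max < params$k_core) return(0)
    core_sub <- igraph::induced_subgraph(sub, which(core >= k_max))
    k_max * undirected_density(igraph::vcount(core_sub),
                               igraph::ecount(core_sub))
  }, numeric(1))
  tibble(gene = igraph::V(g)$name, weight = w)
}

score_complex <- function(g, nodes) {
  sub <- igraph::induced_subgraph(g, nodes)
  n <- as.integer(igraph::vcount(sub))
  e <- as.integer(igraph::ecount(sub))
  dens <- undirected_density(n, e)
  tibble(n_nodes = n, undirected_edges = e, ordered_pairs = 2L * e,
         density = dens, score = dens * n)
}

#' MCODE complex detection
#'
#' Unvisited vertices are taken as seeds in decreasing weight order. From
#' each seed a breadth-first expansion (up to `max_depth`) admits neighbors
#' whose weight is at least `(1 - node_score_cutoff)` times the seed weight;
#' a vertex can belong to at most one complex. Finished complexes optionally
#' lose their degree-1 vertices (haircut) and are scored as density times
#' node count, where density is computed over ordered vertex pairs
#' (`2e / (n (n - 1))`), so a complete module on n nodes scores exactly n.
#'
#' @param g An [igraph::graph].
#' @param weights Optional precomputed [mcode_vertex_weights()] tibble.
#' @param params An [mcode_params()].
#' @return Tibble, one row per complex sorted by score descending:
#'   `module_id`, `nodes` (list column), `n_nodes`, `undirected_edges`,
#'   `ordered_pairs`, `density`, `score`.
#' @export
mcode_find_complexes <- function(g, weights = NULL, params = mcode_params()) {
  if (igraph::vcount(g) == 0) {
    return(tibble(module_id = integer(), nodes = list(), n_nodes = integer(),
                  undirected_edges = integer(), ordered_pairs = integer(),
                  density = numeric(), score = numeric()))
  }
  weights <- weights %||% mcode_vertex_weights(g, params)
  w <- setNames(weights$weight, weights$gene)[igraph::V(g)$name]
  visited <- rep(FALSE, igraph::vcount(g))
  complexes <- list()
  for (seed in order(-w)) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- (1 - params$node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (nb in as.integer(igraph::neighbors(g, v))) {
          if (!visited[nb] && w[nb] >= thr) {
            visited[nb] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (params$haircut && length(members) > 2) {
      sub <- igraph::induced_subgraph(g, members)
      keep <- igraph::degree(sub) >= 2
      members <- members[keep]
    }
    if (length(members) >= 2) complexes[[length(complexes) + 1]] <- members
  }
  if (length(complexes) == 0) {
    return(tibble(module_id = integer(), nodes = list(), n_nodes = integer(),
                  undirected_edges = integer(), ordered_pairs = integer(),
                  density = numeric(), score = numeric()))
  }
  out <- purrr::map_dfr(complexes, function(m) {
    sc <- score_complex(g, m)
    sc$nodes <- list(sort(igraph::V(g)$name[m]))
    sc
  }) %>%
    arrange(desc(.data$score), desc(.data$n_nodes)) %>%
    mutate(module_id = row_number()) %>%
    select("module_id", "nodes", "n_nodes", "undirected_edges",
           "ordered_pairs", "density", "score")
  out
}

#' Select hub modules and pool their genes
#'
#' Keeps complexes with score at least `score_min` and at least `nodes_min`
#' nodes; returns the union of their node sets.
#'
#' @param modules Tibble from [mcode_find_complexes()].
#' @param score_min Minimum MCODE score, default 6.
#' @param nodes_min Minimum node count, default 6.
#' @return List with `modules` (the qualifying rows) and `genes` (sorted
#'   union of their members).
#' @export
select_hub_modules <- function(modules, score_min = 6, nodes_min = 6) {
  keep <- filter(modules, .data$score >= score_min, .data$n_nodes >= nodes_min)
  if (nrow(keep) == 0) {
    warnf("no module meets score >= %g and nodes >= %g", score_min, nodes_min)
  }
  list(modules = keep, genes = sort(unique(unlist(keep$nodes))))
}
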