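test_that("graph construction filters, rescales, and deduplicates", {
  edges <- tibble::tibble(gene_a = c("A", "C", "E", "E", "G"),
                          gene_b = c("B", "D", "F", "F", "G"),
                          confidence = c(0.69, 0.70, 0.95, 0.80, 0.99))
  g <- build_ppi_graph(edges)
  expect_equal(igraph::ecount(g), 2)           # 0.69 out, self-loop out
  expect_false("A" %in% igraph::V(g)$name)          # isolated nodes excluded
  ef <- igraph::as_data_frame(g)
  expect_equal(ef$confidence[ef$from == "E" | ef$to == "E"], 0.95) # max kept
  string_scale <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                 confidence = c(700, 420))
  gs <- build_ppi_graph(string_scale)
  expect_equal(igraph::ecount(gs), 1)          # 700 -> 0.70 retained
  expect_error(build_ppi_graph(tibble::tibble(gene_a = "A", gene_b = "B",
                                              confidence = NA)),
               "malformed")
})

test_that("MCC matches hand-evaluated small graphs", {
  tri <- build_ppi_graph(complete_graph_edges(c("a", "b", "c")))
  expect_true(all(mcc_scores(tri)$mcc == 2))        # (3-1)! per node
  path <- build_ppi_graph(tibble::tibble(gene_a = c("a", "b"),
                                         gene_b = c("b", "c"),
                                         confidence = 1))
  sc <- mcc_scores(path)
  expect_equal(sc$mcc[sc$gene == "B"], 2)
  expect_equal(sc$mcc[sc$gene %in% c("A", "C")], c(1, 1))
  k4 <- build_ppi_graph(complete_graph_edges(letters[1:4]))
  expect_true(all(mcc_scores(k4)$mcc == 6))         # (4-1)!
})

test_that("MCC equals degree on triangle-free graphs", {
  set.seed(20)
  for (i in 1:10) {
    g <- igraph::sample_tree(sample(10:50, 1))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    sc <- mcc_scores(g)
    expect_equal(sc$mcc, sc$degree, info = paste("tree", i))
  }
  g <- igraph::sample_bipartite(12, 12, p = 0.3)
  igraph::V(g)$name <- paste0("v", 1:24)
  sc <- mcc_scores(g)
  expect_equal(sc$mcc, sc$degree)
})

test_that("MCC agrees with the brute-force subset-enumeration oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.7))
    g <- graph_from_adjacency_named(adj)
    sc <- mcc_scores(g)
    oracle <- mcc_bruteforce(adj)
    got <- setNames(sc$mcc, sc$gene)[names(oracle)]
    # nodes in no clique of size >= 2 score 0 in both
    expect_equal(unname(got), unname(oracle), info = paste("graph", i))
  }
})

test_that("clique budget errors instead of truncating", {
  g <- build_ppi_graph(complete_graph_edges(paste0("n", 1:10)))
  expect_error(mcc_scores(g, clique_budget = 0), "budget")
})

test_that("hub selection takes the top k with documented tie-breaks", {
  set.seed(22)
  scores <- tibble::tibble(gene = paste0("g", 1:25),
                           mcc = c(100:77, 77),
                           degree = c(rep(5, 24), 9))
  hubs <- top_k_hubs(scores, k = 20)
  expect_identical(nrow(hubs), 20L)
  expect_identical(hubs$rank, 1:20)
  expect_true(all(hubs$mcc >= sort(scores$mcc, decreasing = TRUE)[20]))
  # tie at the boundary: higher degree wins
  tie <- tibble::tibble(gene = c("aa", "zz"), mcc = c(7, 7),
                        degree = c(1, 4))
  expect_identical(top_k_hubs(tie, k = 1)$gene, "zz")
  expect_warning(top_k_hubs(scores, k = 30), "only 25")
})

test_that("MCODE vertex weights match hand-evaluated cases", {
  k7 <- build_ppi_graph(complete_graph_edges(paste0("m", 1:7)))
  w <- mcode_vertex_weights(k7)
  expect_true(all(w$weight == 6))   # core level 6, density 1
  # star center: neighborhood has no 2-core
  star <- build_ppi_graph(tibble::tibble(gene_a = "hub",
                                         gene_b = paste0("leaf", 1:5),
                                         confidence = 1))
  w2 <- mcode_vertex_weights(star)
  expect_true(all(w2$weight == 0))  # leaves by degree cutoff, center by core
})

test_that("MCODE recovers planted cliques with the expected scores", {
  set.seed(23)
  k7 <- paste0("a", 1:7)
  k6 <- paste0("b", 1:6)
  bg <- paste0("x", 1:20)
  edges <- dplyr::bind_rows(
    complete_graph_edges(k7),
    complete_graph_edges(k6),
    tibble::tibble(gene_a = sample(bg, 15, replace = TRUE),
                   gene_b = sample(c(bg, k7[1], k6[1]), 15, replace = TRUE),
                   confidence = 1))
  g <- build_ppi_graph(dplyr::filter(edges, gene_a != gene_b))
  mods <- mcode_find_complexes(g)
  expect_gte(nrow(mods), 2)
  expect_identical(mods$nodes[[1]], toupper(k7))
  expect_identical(mods$nodes[[2]], toupper(k6))
  expect_equal(mods$score[1:2], c(7, 6))
  expect_identical(mods$ordered_pairs[1:2], c(42L, 30L))
  expect_true(all(mods$density >= 0 & mods$density <= 1))
  # complexes are vertex-disjoint
  all_nodes <- unlist(mods$nodes)
  expect_false(any(duplicated(all_nodes)))
  # every complex node has positive weight
  w <- mcode_vertex_weights(g)
  expect_true(all(setNames(w$weight, w$gene)[all_nodes] > 0))
  sel <- select_hub_modules(mods)
  expect_identical(sel$genes, sort(toupper(c(k7, k6))))
  expect_identical(nrow(sel$modules), 2L)
})

test_that("module selection applies both cutoffs and warns when empty", {
  mods <- tibble::tibble(module_id = 1:2, nodes = list(paste0("a", 1:5),
                                                       paste0("b", 1:7)),
                         n_nodes = c(5L, 7L), undirected_edges = c(10L, 21L),
                         ordered_pairs = c(20L, 42L), density = c(1, 1),
                         score = c(5, 7))
  sel <- select_hub_modules(mods)
  expect_identical(sel$modules$module_id, 2L)      # n=5 dropped by nodes_min
  expect_warning(select_hub_modules(mods[1, ]), "no module")
  empty <- mcode_find_complexes(igraph::make_empty_graph(0, directed = FALSE))
  expect_identical(nrow(empty), 0L)
})
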