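test_that("platform universes share the core and keep private genes", {
  cfg <- synth_config(universe_size = 120, shared_core_size = 100)
  u <- generate_platform_universes(cfg)
  sets <- split(u$gene, u$platform)
  expect_length(sets, 3)
  expect_true(all(vapply(sets, length, integer(1)) == 120))
  core <- u$gene[u$platform == 1 & u$is_core]
  expect_length(core, 100)
  for (s in sets) expect_true(all(core %in% s))
  # pairwise intersections contain at least the core; privates differ
  expect_gte(length(intersect(sets[[1]], sets[[2]])), 100)
  expect_gt(length(setdiff(sets[[1]], sets[[2]])), 0)
})

test_that("degenerate core = universe gives identical platform sets", {
  cfg <- synth_config(universe_size = 50, shared_core_size = 50)
  u <- generate_platform_universes(cfg)
  sets <- split(u$gene, u$platform)
  expect_identical(sort(sets[[1]]), sort(sets[[2]]))
  expect_identical(sort(sets[[2]]), sort(sets[[3]]))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(universe_size = 50, shared_core_size = 60),
               "exceeds")
  expect_error(generate_expression_dataset(small_config(), platform = 9, 1),
               "unknown platform")
  expect_error(synth_config(planted_module_genes = c("NOPE")),
               "subset")
})

test_that("identical config and seed reproduce every artifact exactly", {
  s1 <- simulate_study(small_config(seed = 42))
  s2 <- simulate_study(small_config(seed = 42))
  expect_identical(s1$datasets[[1]]$values, s2$datasets[[1]]$values)
  expect_identical(s1$ppi_edges, s2$ppi_edges)
  expect_identical(s1$survival$clinical, s2$survival$clinical)
  expect_identical(s1$literature, s2$literature)
  s3 <- simulate_study(small_config(seed = 43))
  expect_false(identical(s1$datasets[[1]]$values, s3$datasets[[1]]$values))
})

test_that("written studies are byte-identical across reruns", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(small_config(seed = 5)), d1)
  write_study(simulate_study(small_config(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted effects appear in the case-minus-control means", {
  cfg <- small_config(seed = 7)
  ds <- generate_expression_dataset(cfg, 1, 1)
  ann <- ds$annotation
  is_case <- ds$groups == "case"
  diffs <- rowMeans(ds$values[, is_case]) - rowMeans(ds$values[, !is_case])
  planted <- cfg$planted_de_genes
  # n = 10/group, noise 0.5: SE of a mean difference is 0.5*sqrt(2/10) = 0.22
  for (i in seq_len(nrow(planted))) {
    probes <- ann$probe[ann$symbol == planted$gene[i]]
    expect_true(all(abs(diffs[probes] - planted$effect[i]) < 0.9),
                info = planted$gene[i])
  }
  null_probes <- ann$probe[!ann$symbol %in% planted$gene & nzchar(ann$symbol)]
  expect_lt(abs(mean(diffs[null_probes])), 0.1)
})

test_that("empirical log2 effects converge to the configured effect", {
  cfg <- synth_config(universe_size = 60, shared_core_size = 40,
                      samples_per_group = 200, seed = 11)
  ds <- generate_expression_dataset(cfg, 1, 1)
  is_case <- ds$groups == "case"
  diffs <- rowMeans(ds$values[, is_case]) - rowMeans(ds$values[, !is_case])
  ann <- ds$annotation
  per_gene <- vapply(cfg$planted_de_genes$gene, function(g) {
    mean(diffs[ann$probe[ann$symbol == g]])
  }, numeric(1))
  err <- per_gene - cfg$planted_de_genes$effect
  expect_lt(abs(mean(err)), 0.1)
  expect_lt(max(abs(err)), 0.25)
})

test_that("probe annotation has the configured multiplicity and blanks", {
  cfg <- small_config(seed = 3, probes_per_gene = 2,
                      blank_probe_fraction = 0.1)
  ds <- generate_expression_dataset(cfg, 2, 1)
  ann <- ds$annotation
  counts <- table(ann$symbol[nzchar(ann$symbol)])
  expect_true(all(counts <= 2))
  # planted genes keep both probes (never blanked)
  expect_true(all(counts[cfg$planted_de_genes$gene] == 2))
  frac_blank <- mean(!nzchar(ann$symbol))
  expect_gt(frac_blank, 0.02)
  expect_lt(frac_blank, 0.2)
})

test_that("PPI generator plants the full clique and respects edge rules", {
  cfg <- small_config(seed = 2, background_edge_prob = 0)
  edges <- generate_ppi_edges(cfg)
  mod <- cfg$planted_module_genes
  expect_identical(nrow(edges), as.integer(choose(length(mod), 2)))
  expect_true(all(edges$gene_a %in% mod & edges$gene_b %in% mod))
  expect_true(all(edges$confidence >= 0.9 & edges$confidence <= 1))
  expect_true(all(edges$gene_a != edges$gene_b))
  expect_false(any(duplicated(paste(edges$gene_a, edges$gene_b))))
  cfg2 <- small_config(seed = 2, background_edge_prob = 0.01)
  e2 <- generate_ppi_edges(cfg2)
  expect_gt(nrow(e2), nrow(edges))
  expect_true(all(e2$confidence > 0 & e2$confidence <= 1))
})

test_that("survival cohort respects censoring configuration", {
  cfg0 <- small_config(seed = 4, censor_rate = 0)
  sv0 <- generate_survival_cohort(cfg0)
  expect_true(all(sv0$clinical$event == 1))
  expect_true(all(sv0$clinical$time > 0))
  cfg3 <- small_config(seed = 4, censor_rate = 0.3)
  sv3 <- generate_survival_cohort(cfg3)
  expect_gt(mean(sv3$clinical$event == 0), 0.15)
  expect_lt(mean(sv3$clinical$event == 0), 0.45)
})

test_that("literature table covers planted genes and uses out-of-universe decoys", {
  cfg <- small_config(seed = 6)
  lit <- load_literature_table(generate_literature_table(cfg))
  genes <- unique(unlist(lit$genes))
  expect_true(all(cfg$planted_de_genes$gene %in% genes))
  universe <- generate_platform_universes(cfg)$gene
  decoys <- setdiff(genes, cfg$planted_de_genes$gene)
  expect_gt(length(decoys), 0)
  expect_length(intersect(decoys, universe), 0)
  gt <- ground_truth(cfg)
  expect_true(all(gt$expected_kgs %in% genes))
  expect_identical(gt$expected_kgs, sort(cfg$planted_module_genes))
})
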