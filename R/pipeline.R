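#' Run the full key-gene identification pipeline
#'
#' Executes, in dependency order: per-dataset differential expression
#' (preprocess, moderated t-test, BH, probe collapsing, thresholding);
#' within-platform union (icDEGs) and across-platform union (gcDEGs);
#' per-gene SVM accuracy filtering (DEDGs); PPI network construction on the
#' DEDGs with MCC hub ranking and MCODE module detection; literature
#' meta-hub union; the three-way key-gene intersection; and per-gene
#' AUC/survival validation plus the necessity analysis. Every threshold used
#' is recorded in the report. Reruns with the same study (or config seed)
#' reproduce all set-valued outputs exactly.
#'
#' @param study A `crosskey_study` from [simulate_study()], or `NULL` to
#'   simulate one from `config`.
#' @param config A [synth_config()], used when `study` is `NULL`.
#' @param fc_threshold,p_threshold DEG thresholds (|log2FC| >= 1.2,
#'   adjusted p < 0.01 by default).
#' @param svm An [svm_settings()] (accuracy threshold 0.95 by default).
#' @param confidence_threshold PPI confidence cutoff (0.70).
#' @param n_hubs Number of MCC hub genes (20).
#' @param mcode An [mcode_params()].
#' @param module_score_min,module_nodes_min Hub-module selection cutoffs
#'   (both 6).
#' @param literature Optional `literature_table` overriding the study's
#'   generated table.
#' @param gmt Optional named list of annotation gene sets; when given, an
#'   over-representation analysis of the DEDGs is run against them.
#' @param validate Run the AUC/survival validation stage (default `TRUE`).
#' @param verbose Log stage progress to standard error.
#' @return A `crosskey_report` list; see [tidy.crosskey_report()] and
#'   [glance.crosskey_report()].
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(config = synth_config(seed = 1))
#' report$kg_report$kgs
#' }
run_pipeline <- function(study = NULL, config = synth_config(),
                         fc_threshold = 1.2, p_threshold = 0.01,
                         svm = NULL,
                         confidence_threshold = 0.70, n_hubs = 20,
                         mcode = mcode_params(),
                         module_score_min = 6, module_nodes_min = 6,
                         literature = NULL, gmt = NULL,
                         validate = TRUE, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message("[crosskey] ", sprintf(...))
  if (is.null(study)) {
    log_stage("simulate: generating synthetic study (seed %d)", config$seed)
    study <- simulate_study(config)
  }
  svm <- svm %||% svm_settings(seed = study$config$seed)

  log_stage("deg: %d datasets", length(study$datasets))
  deg_tables <- purrr::map(study$datasets, function(ds) {
    run_deg(ds, fc_threshold = fc_threshold, p_threshold = p_threshold)
  })
  deg_sets <- purrr::map(deg_tables, function(tb) {
    filter(tb, .data$is_deg) %>% select("gene", "direction")
  })

  platforms <- vapply(study$datasets, function(d) as.character(d$platform),
                      character(1))
  by_platform <- split(deg_sets, platforms)
  ic_sets <- purrr::imap(by_platform, union_within_platform)
  gc_set <- union_across_platforms(ic_sets)
  log_stage("combine: %s icDEGs -> %d gcDEGs",
            paste(vapply(ic_sets, nrow, integer(1)), collapse = "/"),
            nrow(gc_set))

  gene_datasets <- purrr::map(study$datasets, function(ds) {
    nm <- ds$name
    gene_level_dataset(ds, deg_tables[[nm]])
  })
  dedg_table <- select_dedgs(gene_datasets, gc_set$gene, svm)
  dedgs <- filter(dedg_table, .data$selected)$gene
  log_stage("dedg: %d of %d gcDEGs pass accuracy > %g",
            length(dedgs), nrow(gc_set), svm$accuracy_threshold)

  edges <- study$ppi_edges %>%
    filter(toupper(.data$gene_a) %in% dedgs, toupper(.data$gene_b) %in% dedgs)
  graph <- build_ppi_graph(edges, confidence_threshold)
  scores <- mcc_scores(graph)
  hubs <- suppressWarnings(top_k_hubs(scores, n_hubs))
  modules <- mcode_find_complexes(graph, params = mcode)
  hub_modules <- suppressWarnings(
    select_hub_modules(modules, module_score_min, module_nodes_min))
  log_stage("network: %d nodes, %d edges; %d hubs, %d module genes",
            igraph::vcount(graph), igraph::ecount(graph), nrow(hubs),
            length(hub_modules$genes))

  lit <- literature %||% load_literature_table(study$literature)
  meta <- meta_hub_union(lit)
  kg_report <- identify_kgs(hubs$gene, hub_modules$genes, meta)
  log_stage("kg: %d key gene(s)", length(kg_report$kgs))

  enrichment <- if (!is.null(gmt)) {
    hypergeometric_ora(dedgs, gmt,
                       universe = unique(unlist(
                         purrr::map(gene_datasets,
                                    function(d) rownames(d$values)))))
  }

  validation <- NULL
  necessity <- NULL
  if (validate && length(kg_report$kgs) > 0) {
    log_stage("validate: %d key genes", length(kg_report$kgs))
    aucs <- purrr::map_dfr(gene_datasets, function(d) {
      auc_by_gene(d$values, d$groups, kg_report$kgs)
    }, .id = "dataset") %>%
      group_by(.data$gene) %>%
      summarise(auc = mean(.data$auc, na.rm = TRUE), .groups = "drop")
    surv <- validate_genes(kg_report$kgs,
                           survival_cohort = study$survival) %>%
      select(-"auc")
    validation <- left_join(aucs, surv, by = "gene")
    necessity <- necessity_analysis(
      kg_report$kgs,
      split(deg_sets, platforms))
  }

  structure(list(
    study = study,
    parameters = list(fc_threshold = fc_threshold,
                      p_threshold = p_threshold,
                      svm = unclass(svm),
                      confidence_threshold = confidence_threshold,
                      n_hubs = n_hubs, mcode = unclass(mcode),
                      module_score_min = module_score_min,
                      module_nodes_min = module_nodes_min,
                      seed = study$config$seed,
                      validate = validate),
    deg_tables = deg_tables,
    deg_sets = deg_sets,
    ic_sets = ic_sets,
    gc_set = gc_set,
    dedg_table = dedg_table,
    dedgs = dedgs,
    graph = graph,
    mcc = scores,
    hubs = hubs,
    modules = modules,
    hub_modules = hub_modules,
    meta = meta,
    kg_report = kg_report,
    enrichment = enrichment,
    validation = validation,
    necessity = necessity
  ), class = "crosskey_report")
}

#' @export
print.crosskey_report <- function(x, ...) {
  cat("<crosskey_report>\n")
  cat(sprintf("  datasets: %d; gcDEGs: %d; DEDGs: %d\n",
              length(x$deg_tables), nrow(x$gc_set), length(x$dedgs)))
  cat(sprintf("  network: %d nodes / %d edges; hubs: %d; module genes: %d; meta-hubs: %d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$hubs), length(x$hub_modules$genes), x$meta$n_normalized))
  cat(sprintf("  key genes (%d): %s\n", length(x$kg_report$kgs),
              paste(x$kg_report$kgs, collapse = ", ")))
  invisible(x)
}

#' Tidy and summarize a pipeline report
#'
#' `tidy()` returns the per-key-gene table (membership flags joined with the
#' validation metrics when present); `glance()` the stage-level sizes.
#'
#' @param x A `crosskey_report`.
#' @param ... Unused.
#' @export
tidy.crosskey_report <- function(x, ...) {
  out <- x$kg_report$membership
  if (!is.null(x$validation)) out <- left_join(out, x$validation, by = "gene")
  out
}

#' @rdname tidy.crosskey_report
#' @export
glance.crosskey_report <- function(x, ...) {
  tibble(n_datasets = length(x$deg_tables),
         n_gcdegs = nrow(x$gc_set),
         n_dedgs = length(x$dedgs),
         n_network_nodes = igraph::vcount(x$graph),
         n_network_edges = igraph::ecount(x$graph),
         n_hubs = nrow(x$hubs),
         n_module_genes = length(x$hub_modules$genes),
         n_meta_hubs = x$meta$n_normalized,
         n_kgs = length(x$kg_report$kgs))
}
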