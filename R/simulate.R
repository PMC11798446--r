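#' Configuration for a synthetic multi-platform study
#'
#' Defines the study layout the generator emulates: several measurement
#' "platforms" with distinct but overlapping gene universes, two case/control
#' datasets per platform, a set of planted differentially expressed genes with
#' known log2 effects, a planted near-clique inside a sparse background PPI
#' network, a survival cohort whose hazard depends on a planted gene, and a
#' literature table of pseudo-studies that contains the planted genes.
#'
#' Defaults describe a study in which the planted signal is strong and
#' recoverable: log2 effect 3 against noise SD 0.5 at 30 samples per group.
#'
#' @param n_platforms Number of platforms.
#' @param datasets_per_platform Datasets (case/control cohorts) per platform.
#' @param universe_size Genes measured per platform.
#' @param shared_core_size Genes shared by all platforms; must not exceed
#'   `universe_size`.
#' @param samples_per_group Samples per group (case and control) per dataset.
#' @param planted_de_genes Data frame with columns `gene`, `effect` (log2
#'   shift of cases minus controls). Planted genes live in the shared core.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param probes_per_gene Integer vector the per-gene probe count is sampled
#'   from.
#' @param blank_probe_fraction Fraction of probes whose annotation symbol is
#'   left blank (mimicking unannotated platform probes). Blank probes are
#'   drawn only among genes with zero planted effect so the planted signal is
#'   never silently removed.
#' @param planted_module_genes Subset of planted genes forming a near-clique
#'   in the PPI network.
#' @param background_edge_prob Probability of a background PPI edge.
#' @param planted_edge_prob Probability of each planted within-module edge.
#' @param survival_n Survival cohort size.
#' @param survival_beta Log hazard per unit (centered) expression of the
#'   designated risk gene.
#' @param survival_gene Designated risk gene; defaults to the first planted
#'   module gene.
#' @param censor_rate Approximate fraction of censored subjects.
#' @param n_literature_studies Pseudo-studies in the literature table.
#' @param seed Master seed; together with the configuration it fully
#'   determines every emitted artifact.
#' @return A `crosskey_config` list.
#' @export
#' @examples
#' cfg <- synth_config(seed = 7)
#' cfg$planted_de_genes
synth_config <- function(n_platforms = 3,
                         datasets_per_platform = 2,
                         universe_size = 200,
                         shared_core_size = 150,
                         samples_per_group = 30,
                         planted_de_genes = NULL,
                         noise_sd = 0.5,
                         probes_per_gene = 1:3,
                         blank_probe_fraction = 0.1,
                         planted_module_genes = NULL,
                         background_edge_prob = 0.005,
                         planted_edge_prob = 1.0,
                         survival_n = 300,
                         survival_beta = 0.7,
                         survival_gene = NULL,
                         censor_rate = 0.3,
                         n_literature_studies = 10,
                         seed = 1) {
  if (shared_core_size > universe_size) {
    stopf("shared_core_size (%d) exceeds universe_size (%d)",
          shared_core_size, universe_size)
  }
  if (shared_core_size < universe_size && universe_size - shared_core_size < 1) {
    stopf("each platform needs at least one private gene")
  }
  if (is.null(planted_de_genes)) {
    planted_de_genes <- tibble(
      gene = sprintf("CG%04d", 1:12),
      effect = c(rep(3, 8), rep(-3, 4))
    )
  }
  planted_de_genes <- as_tibble(planted_de_genes)
  stopifnot(all(c("gene", "effect") %in% names(planted_de_genes)))
  if (is.null(planted_module_genes)) {
    planted_module_genes <- planted_de_genes$gene[1:min(7, nrow(planted_de_genes))]
  }
  if (!all(planted_module_genes %in% planted_de_genes$gene)) {
    stopf("planted_module_genes must be a subset of planted_de_genes")
  }
  core <- sprintf("CG%04d", seq_len(shared_core_size))
  if (!all(planted_de_genes$gene %in% core)) {
    stopf("planted genes must lie within the shared core (CG0001..CG%04d)",
          shared_core_size)
  }
  structure(list(
    n_platforms = n_platforms,
    datasets_per_platform = datasets_per_platform,
    universe_size = universe_size,
    shared_core_size = shared_core_size,
    samples_per_group = samples_per_group,
    planted_de_genes = planted_de_genes,
    noise_sd = noise_sd,
    probes_per_gene = probes_per_gene,
    blank_probe_fraction = blank_probe_fraction,
    planted_module_genes = planted_module_genes,
    background_edge_prob = background_edge_prob,
    planted_edge_prob = planted_edge_prob,
    survival_n = survival_n,
    survival_beta = survival_beta,
    survival_gene = survival_gene %||% planted_module_genes[1],
    censor_rate = censor_rate,
    n_literature_studies = n_literature_studies,
    seed = seed
  ), class = "crosskey_config")
}

#' Per-platform gene universes
#'
#' Each platform measures the shared core plus its own private genes, so
#' platforms overlap without coinciding — the situation that motivates
#' union-based (rather than intersection-based) cross-platform analysis.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `platform`, `gene`, `is_core`.
#' @export
generate_platform_universes <- function(config) {
  core <- sprintf("CG%04d", seq_len(config$shared_core_size))
  n_priv <- config$universe_size - config$shared_core_size
  purrr::map_dfr(seq_len(config$n_platforms), function(p) {
    priv <- if (n_priv > 0) sprintf("P%dG%04d", p, seq_len(n_priv)) else character()
    tibble(platform = p,
           gene = c(core, priv),
           is_core = c(rep(TRUE, length(core)), rep(FALSE, length(priv))))
  })
}

platform_universe <- function(config, platform) {
  if (!platform %in% seq_len(config$n_platforms)) {
    stopf("unknown platform id %s (config has %d platforms)",
          platform, config$n_platforms)
  }
  u <- generate_platform_universes(config)
  u$gene[u$platform == platform]
}

# Probe design for one platform: shared by both of its datasets, like a real
# array design. A `blank_probe_fraction` of probes (drawn among zero-effect
# genes) gets an empty annotation symbol.
platform_probe_design <- function(config, platform) {
  genes <- platform_universe(config, platform)
  with_stream(config$seed, "annot", platform, code = {
    n_probes <- if (length(config$probes_per_gene) == 1) {
      rep(config$probes_per_gene, length(genes))
    } else {
      sample(config$probes_per_gene, length(genes), replace = TRUE)
    }
    probes <- tibble(
      gene = rep(genes, n_probes)
    ) %>%
      group_by(.data$gene) %>%
      mutate(probe_rank = row_number()) %>%
      ungroup() %>%
      mutate(probe = sprintf("PR%d_%05d", platform, row_number()),
             symbol = .data$gene)
    null_genes <- setdiff(genes, config$planted_de_genes$gene)
    blankable <- which(probes$gene %in% null_genes)
    n_blank <- round(config$blank_probe_fraction * nrow(probes))
    if (n_blank > 0 && length(blankable) > 0) {
      blank_idx <- sample(blankable, min(n_blank, length(blankable)))
      probes$symbol[blank_idx] <- ""
    }
    baseline <- setNames(runif(length(genes), 4, 10), genes)
    probes$baseline <- baseline[probes$gene]
    probes
  })
}

#' An expression dataset container
#'
#' Holds a probe-by-sample matrix of (log2-scale) expression values together
#' with sample group labels, a platform tag, and a probe-to-symbol
#' annotation.
#'
#' @param values Numeric probe x sample matrix with unique rownames (probe
#'   ids) and colnames (sample ids).
#' @param groups Character/factor vector of per-sample labels, values
#'   `"case"` or `"control"`, length `ncol(values)`.
#' @param platform Platform tag.
#' @param annotation Data frame with columns `probe`, `symbol` (symbol may be
#'   blank).
#' @param name Dataset label.
#' @return A `crosskey_dataset` object.
#' @export
expression_dataset <- function(values, groups, platform = NA,
                               annotation = NULL, name = "dataset") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("probe ids (rownames) must be present and unique")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stopf("groups length (%d) != number of samples (%d)",
          length(groups), ncol(values))
  }
  if (anyNA(groups)) stopf("missing group labels")
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad)) stopf("unknown group labels: %s", paste(bad, collapse = ", "))
  if (any(table(factor(groups, c("case", "control"))) < 2)) {
    stopf("need at least 2 samples per group")
  }
  structure(list(values = values, groups = groups, platform = platform,
                 annotation = if (!is.null(annotation)) as_tibble(annotation),
                 name = name),
            class = "crosskey_dataset")
}

#' @export
print.crosskey_dataset <- function(x, ...) {
  cat(sprintf("<crosskey_dataset '%s'> platform %s: %d probes x %d samples (%d case / %d control)\n",
              x$name, x$platform, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Generate one synthetic expression dataset
#'
#' Values are drawn on the log2 scale as `baseline(gene, platform) +
#' effect(gene) * is_case + N(0, noise_sd^2)`, with per-gene platform
#' baselines Uniform(4, 10) so absolute levels differ between platforms.
#' Every probe of a gene shares that gene's baseline and effect.
#'
#' @param config A [synth_config()].
#' @param platform Platform id (1-based).
#' @param replicate Dataset replicate id within the platform (1-based).
#' @return A [expression_dataset()] with attached annotation.
#' @export
generate_expression_dataset <- function(config, platform, replicate) {
  design <- platform_probe_design(config, platform)
  effects <- setNames(rep(0, config$universe_size),
                      platform_universe(config, platform))
  effects[config$planted_de_genes$gene] <- config$planted_de_genes$effect
  n <- config$samples_per_group
  groups <- rep(c("case", "control"), each = n)
  sample_ids <- sprintf("S%d.%d_%s%02d", platform, replicate,
                        ifelse(groups == "case", "T", "N"),
                        c(seq_len(n), seq_len(n)))
  vals <- with_stream(config$seed, "expr", platform, replicate, code = {
    mu <- outer(design$baseline, rep(1, 2 * n)) +
      outer(effects[design$gene], as.numeric(groups == "case"))
    mu + matrix(rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
  })
  rownames(vals) <- design$probe
  colnames(vals) <- sample_ids
  expression_dataset(vals, groups, platform = platform,
                     annotation = design[, c("probe", "symbol")],
                     name = sprintf("platform%d_dataset%d", platform, replicate))
}

#' Generate the synthetic weighted PPI edge list
#'
#' Planted module genes are pairwise connected with probability
#' `planted_edge_prob` and confidence Uniform(0.9, 1); all other unordered
#' pairs over the union of platform universes are connected with probability
#' `background_edge_prob` and confidence Uniform(0.2, 0.95). No self-loops or
#' duplicate pairs are emitted.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `gene_a`, `gene_b`, `confidence`.
#' @export
generate_ppi_edges <- function(config) {
  genes <- sort(unique(generate_platform_universes(config)$gene))
  mod <- sort(config$planted_module_genes)
  with_stream(config$seed, "ppi", code = {
    pairs <- t(utils::combn(genes, 2))
    in_module <- pairs[, 1] %in% mod & pairs[, 2] %in% mod
    keep_planted <- in_module &
      rbinom(nrow(pairs), 1, config$planted_edge_prob) == 1
    keep_bg <- !in_module &
      rbinom(nrow(pairs), 1, config$background_edge_prob) == 1
    conf <- numeric(nrow(pairs))
    conf[keep_planted] <- runif(sum(keep_planted), 0.9, 1)
    conf[keep_bg] <- runif(sum(keep_bg), 0.2, 0.95)
    keep <- keep_planted | keep_bg
    tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
           confidence = conf[keep])
  })
}

#' Generate a synthetic survival cohort
#'
#' Event times are exponential with log hazard `survival_beta` per unit of
#' the centered expression of the designated risk gene; censoring times are
#' independent Uniform(0, T_max) with T_max solved numerically so the
#' expected censored fraction approximates `censor_rate`.
#'
#' @param config A [synth_config()].
#' @param expression Optional gene x sample matrix to take the risk-gene
#'   expression from; when `NULL` a cohort expression matrix over the planted
#'   genes is generated (values N(6, 1) on the log2 scale).
#' @return List with `clinical` (tibble: `sample`, `time`, `event`,
#'   `risk_score`) and `expression` (gene x sample matrix).
#' @export
generate_survival_cohort <- function(config, expression = NULL) {
  with_stream(config$seed, "survival", code = {
    if (is.null(expression)) {
      genes <- config$planted_de_genes$gene
      n <- config$survival_n
      expression <- matrix(rnorm(length(genes) * n, 6, 1),
                           nrow = length(genes),
                           dimnames = list(genes, sprintf("SV%04d", seq_len(n))))
    }
    if (!config$survival_gene %in% rownames(expression)) {
      stopf("risk gene %s absent from cohort expression", config$survival_gene)
    }
    x <- expression[config$survival_gene, ]
    lambda <- 0.1 * exp(config$survival_beta * (x - mean(x)))
    t_event <- rexp(length(x), rate = lambda)
    if (config$censor_rate <= 0) {
      time <- t_event
      event <- rep(1L, length(x))
    } else {
      # P(censored | Tmax) = mean_i (1 - exp(-lambda_i * Tmax)) / (lambda_i * Tmax)
      p_cens <- function(tm) mean((1 - exp(-lambda * tm)) / (lambda * tm))
      t_max <- uniroot(function(tm) p_cens(tm) - config$censor_rate,
                       interval = c(1e-6, 1e6), tol = 1e-8)$root
      c_time <- runif(length(x), 0, t_max)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    }
    list(clinical = tibble(sample = colnames(expression), time = time,
                           event = event, risk_score = as.numeric(x)),
         expression = expression)
  })
}

#' Generate a synthetic literature hub-gene table
#'
#' Emits pseudo-studies whose gene lists jointly cover all planted genes plus
#' decoy symbols absent from every platform universe, mirroring the structure
#' of a curated table of previously reported hub genes.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `study_id`, `platform`, `genes`
#'   (semicolon-separated symbol string).
#' @export
generate_literature_table <- function(config) {
  planted <- config$planted_de_genes$gene
  decoys <- sprintf("FAKE%02d", 1:15)
  n_st <- max(config$n_literature_studies, 1)
  with_stream(config$seed, "literature", code = {
    assigned <- split(planted, rep_len(seq_len(n_st), length(planted)))
    rows <- purrr::map_dfr(seq_len(n_st), function(i) {
      extra_planted <- sample(planted, rbinom(1, length(planted), 0.3))
      gl <- unique(c(assigned[[as.character(i)]] %||% character(),
                     extra_planted,
                     sample(decoys, 1 + rbinom(1, 4, 0.5))))
      tibble(study_id = sprintf("synthstudy%02d", i),
             platform = sample(c("Affy.", "Illum.", "Agil."), 1),
             genes = paste(sample(gl), collapse = "; "))
    })
    rows
  })
}

#' Ground truth of a synthetic study
#'
#' @param config A [synth_config()].
#' @return List with `de_genes` (tibble gene/effect), `module_genes`,
#'   `expected_kgs` (= planted DE genes that are module genes and appear in
#'   the literature table, i.e. the module genes by construction).
#' @export
ground_truth <- function(config) {
  lit <- meta_hub_union(load_literature_table(generate_literature_table(config)))
  list(
    de_genes = config$planted_de_genes,
    module_genes = config$planted_module_genes,
    expected_kgs = sort(intersect(intersect(config$planted_de_genes$gene,
                                            config$planted_module_genes),
                                  lit$genes))
  )
}

#' Simulate a complete multi-platform study
#'
#' Bundles every artifact the pipeline consumes: per-platform universes, the
#' expression datasets with annotation, the PPI edge list, a survival cohort,
#' a literature table, and the planted ground truth. Identical config and
#' seed give identical output.
#'
#' @param config A [synth_config()].
#' @return A `crosskey_study` list.
#' @export
#' @examples
#' study <- simulate_study(synth_config(universe_size = 60,
#'                                      shared_core_size = 40,
#'                                      samples_per_group = 10, seed = 1))
#' names(study$datasets)
simulate_study <- function(config = synth_config()) {
  datasets <- list()
  for (p in seq_len(config$n_platforms)) {
    for (r in seq_len(config$datasets_per_platform)) {
      ds <- generate_expression_dataset(config, p, r)
      datasets[[ds$name]] <- ds
    }
  }
  structure(list(
    config = config,
    universes = generate_platform_universes(config),
    datasets = datasets,
    ppi_edges = generate_ppi_edges(config),
    survival = generate_survival_cohort(config),
    literature = generate_literature_table(config),
    ground_truth = ground_truth(config)
  ), class = "crosskey_study")
}

#' @export
print.crosskey_study <- function(x, ...) {
  cat(sprintf("<crosskey_study> %d platforms x %d datasets, %d planted DE genes (module: %d), seed %d\n",
              x$config$n_platforms, x$config$datasets_per_platform,
              nrow(x$config$planted_de_genes),
              length(x$config$planted_module_genes), x$config$seed))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Expression, label, annotation, edge, survival and literature tables as
#' TSV, plus the ground truth as JSON.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (nm in names(study$datasets)) {
    ds <- study$datasets[[nm]]
    expr <- data.frame(probe = rownames(ds$values), ds$values,
                       check.names = FALSE)
    tsv(expr, paste0(nm, "_expr.tsv"))
    tsv(data.frame(sample = colnames(ds$values), group = ds$groups),
        paste0(nm, "_labels.tsv"))
    tsv(ds$annotation, paste0(nm, "_annot.tsv"))
  }
  tsv(study$ppi_edges, "ppi_edges.tsv")
  tsv(study$survival$clinical[, c("sample", "time", "event")], "survival.tsv")
  tsv(study$literature, "literature.tsv")
  jsonlite::write_json(study$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
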