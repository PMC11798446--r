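# Gene sets are plain tibbles with a `gene` column and optionally a
# `direction` column; bare character vectors are accepted everywhere and
# coerced. Symbols are case-folded (normalize_symbols()) before any algebra.

as_gene_tbl <- function(x) {
  if (is.character(x)) return(tibble(gene = normalize_symbols(x)))
  x <- as_tibble(x)
  stopifnot("gene" %in% names(x))
  x$gene <- toupper(trimws(x$gene))
  x %>% filter(nzchar(.data$gene)) %>% distinct(.data$gene, .keep_all = TRUE)
}

union_tbls <- function(sets) {
  tbls <- purrr::map(sets, as_gene_tbl)
  all <- bind_rows(tbls)
  if ("direction" %in% names(all)) {
    all %>%
      group_by(.data$gene) %>%
      summarise(direction = if (dplyr::n_distinct(stats::na.omit(.data$direction)) > 1)
        "discordant" else dplyr::first(stats::na.omit(.data$direction)),
        .groups = "drop") %>%
      arrange(.data$gene)
  } else {
    tibble(gene = sort(unique(all$gene)))
  }
}

#' Union of DEG sets within one platform (individual combined DEGs)
#'
#' The icDEG set of a platform is the union of the DEG sets of its datasets:
#' a gene called in either dataset is retained. Genes called in opposite
#' directions are kept with direction `"discordant"`.
#'
#' @param deg_sets List of gene sets (character vectors or tibbles with a
#'   `gene` and optional `direction` column), one per dataset of the
#'   platform.
#' @param platform Provenance label.
#' @return Tibble `gene` (+ `direction` when available) with attribute
#'   `"provenance"`.
#' @export
#' @examples
#' union_within_platform(list(c("A", "B"), c("B", "C")))
union_within_platform <- function(deg_sets, platform = "platform") {
  if (length(deg_sets) == 0) stopf("need at least one DEG set")
  out <- union_tbls(deg_sets)
  attr(out, "provenance") <- as.character(platform)
  out
}

#' Union of icDEG sets across platforms (grand combined DEGs)
#'
#' @param ic_sets List of per-platform icDEG sets.
#' @return Tibble as in [union_within_platform()], provenance `"gcDEG"`.
#' @export
union_across_platforms <- function(ic_sets) {
  if (length(ic_sets) == 0) stopf("need at least one icDEG set")
  out <- union_tbls(ic_sets)
  attr(out, "provenance") <- "gcDEG"
  out
}

#' Intersection of gene sets
#'
#' @param sets List of two or more gene sets.
#' @return Tibble `gene` of symbols present in every input set.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2) stopf("need at least two sets to intersect")
  genes <- purrr::map(sets, function(s) as_gene_tbl(s)$gene)
  tibble(gene = sort(purrr::reduce(genes, intersect)))
}

#' Venn region counts for up to six gene sets
#'
#' @param sets Named (or unnamed) list of 2-6 gene sets.
#' @return List with `regions` (tibble: `pattern` of 0/1 membership flags in
#'   input order, per-set logical columns, `count`) and `union_size`.
#' @export
#' @examples
#' venn_counts(list(A = c("A", "B"), B = c("B", "C")))
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 6) {
    stopf("venn_counts supports 2 to 6 sets (got %d)", length(sets))
  }
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  nm[!nzchar(nm)] <- paste0("set", which(!nzchar(nm)))
  genes <- purrr::map(sets, function(s) as_gene_tbl(s)$gene)
  all_genes <- sort(unique(unlist(genes)))
  member <- vapply(genes, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, nm))
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  regions <- tibble(pattern = names(counts),
                    count = as.integer(counts))
  for (j in seq_along(nm)) {
    regions[[nm[j]]] <- substr(regions$pattern, j, j) == "1"
  }
  list(regions = arrange(regions, desc(.data$count)),
       union_size = length(all_genes))
}

#' Necessity analysis of the key genes
#'
#' Checks, for each key gene, whether the commonly used intersection-based
#' constructions would have retained it: the per-platform common DEG sets
#' (intersection of each platform's datasets), the all-dataset common set,
#' and the union-based grand combined set. Full recovery only under the
#' union construction is the argument for platform-independent analysis.
#'
#' @param kgs Gene set of key genes.
#' @param deg_sets Nested list: one element per platform, each a list of
#'   per-dataset DEG sets.
#' @return List with `membership` (tibble: `gene`, one logical column per
#'   construction) and `recovered` (tibble: `construction`, `n_recovered`).
#' @export
necessity_analysis <- function(kgs, deg_sets) {
  kg <- as_gene_tbl(kgs)$gene
  per_platform <- purrr::imap(deg_sets, function(ds_list, p) {
    intersect_gene_sets(ds_list)$gene
  })
  names(per_platform) <- paste0("common_",
                                names(deg_sets) %||% paste0("platform", seq_along(deg_sets)))
  all_ds <- purrr::flatten(deg_sets)
  constructions <- c(
    per_platform,
    list(common_all = intersect_gene_sets(all_ds)$gene,
         gcDEG = union_across_platforms(
           purrr::map(deg_sets, union_within_platform))$gene)
  )
  membership <- tibble(gene = kg)
  for (nm in names(constructions)) {
    membership[[nm]] <- kg %in% constructions[[nm]]
  }
  list(
    membership = membership,
    recovered = tibble(
      construction = names(constructions),
      n_recovered = vapply(unname(constructions),
                           function(s) sum(kg %in% s), integer(1))
    )
  )
}
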