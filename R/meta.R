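#' Load a literature hub-gene table
#'
#' Reads a table of previously reported hub-gene lists (one study per row,
#' genes as a separator-joined string), tokenizes on commas, semicolons and
#' whitespace, uppercases, and passes tokens through an alias map that fixes
#' evident typographical variants (an alias value may itself be a
#' semicolon-joined list, for tokens that fused two symbols). Tokens shorter
#' than two characters that no alias resolves are flagged as unresolved, not
#' silently dropped.
#'
#' @param path Path to a TSV with columns `study_id`, `platform` (optional)
#'   and `genes`, or a data frame of the same shape.
#' @param alias Path to a two-column TSV (`raw`, `normalized`) or a data
#'   frame; `NULL` for no aliasing.
#' @return A `literature_table` tibble: `study_id`, `platform`, `genes`
#'   (list column of normalized symbols), `unresolved` (list column of
#'   flagged tokens), with the alias map as attribute `"alias"`.
#' @export
#' @examples
#' lit <- load_literature_table(crosskey_extdata("hcc_literature_hubs.tsv"),
#'                              crosskey_extdata("hcc_hub_aliases.tsv"))
#' meta_hub_union(lit)$n_normalized
load_literature_table <- function(path, alias = NULL) {
  tab <- if (is.data.frame(path)) as_tibble(path) else {
    if (!file.exists(path)) stopf("literature table not found: %s", path)
    as_tibble(read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE))
  }
  if (!all(c("study_id", "genes") %in% names(tab))) {
    stopf("literature table needs columns study_id and genes")
  }
  if (anyDuplicated(tab$study_id)) stopf("study_ids must be unique")
  if (any(!nzchar(trimws(tab$genes)))) {
    stopf("empty gene list in study %s",
          tab$study_id[!nzchar(trimws(tab$genes))][1])
  }
  alias_tbl <- if (is.null(alias)) {
    tibble(raw = character(), normalized = character())
  } else if (is.data.frame(alias)) {
    as_tibble(alias)
  } else {
    as_tibble(read.delim(alias, stringsAsFactors = FALSE))
  }
  amap <- setNames(toupper(alias_tbl$normalized), toupper(alias_tbl$raw))
  parse_one <- function(s) {
    toks <- toupper(unlist(strsplit(s, "[,;[:space:]]+")))
    toks <- toks[nzchar(toks)]
    resolved <- unlist(lapply(toks, function(t) {
      if (t %in% names(amap)) strsplit(amap[[t]], ";")[[1]] else t
    }))
    unresolved <- unique(resolved[nchar(resolved) < 2])
    list(raw_tokens = unique(toks),
         genes = sort(unique(resolved[nchar(resolved) >= 2])),
         unresolved = unresolved)
  }
  parsed <- purrr::map(tab$genes, parse_one)
  out <- tibble(
    study_id = as.character(tab$study_id),
    platform = as.character(tab$platform %||% NA_character_),
    genes = purrr::map(parsed, "genes"),
    unresolved = purrr::map(parsed, "unresolved"),
    raw_tokens = purrr::map(parsed, "raw_tokens")
  )
  attr(out, "alias") <- amap
  class(out) <- c("literature_table", class(out))
  out
}

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return Full file path.
#' @export
crosskey_extdata <- function(file = "") {
  system.file("extdata", file, package = "crosskey", mustWork = nzchar(file))
}

#' The packaged literature hub-gene snapshot
#'
#' The table of 48 prior hub-gene studies shipped with the package, loaded
#' with its curated alias map.
#'
#' @return A `literature_table`, see [load_literature_table()].
#' @export
hcc_literature_hubs <- function() {
  load_literature_table(crosskey_extdata("hcc_literature_hubs.tsv"),
                        crosskey_extdata("hcc_hub_aliases.tsv"))
}

#' Meta-hub gene set: union over literature studies
#'
#' Every gene reported as a hub by at least one prior study. Because the
#' counting rule behind a published total may or may not correct typos,
#' three counts are reported: unique raw tokens, unique normalized symbols,
#' and distinct normalized tokens (normalized symbols plus flagged
#' unresolved fragments).
#'
#' @param table A `literature_table` from [load_literature_table()].
#' @return List: `genes` (sorted union of normalized symbols),
#'   `unresolved` (flagged fragments), `n_raw`, `n_normalized`,
#'   `n_normalized_tokens`.
#' @export
meta_hub_union <- function(table) {
  if (!inherits(table, "literature_table")) {
    stopf("expected a literature_table; see load_literature_table()")
  }
  if (nrow(table) == 0) stopf("empty literature table")
  genes <- sort(unique(unlist(table$genes)))
  unresolved <- sort(unique(unlist(table$unresolved)))
  n_raw <- length(unique(unlist(table$raw_tokens)))
  structure(list(genes = genes, unresolved = unresolved,
                 n_raw = n_raw,
                 n_normalized = length(genes),
                 n_normalized_tokens = length(genes) + length(unresolved)),
            class = "meta_hub_set")
}

#' @export
print.meta_hub_set <- function(x, ...) {
  cat(sprintf("<meta_hub_set> %d normalized symbols (+%d unresolved fragment(s) = %d tokens)\n",
              x$n_normalized, length(x$unresolved), x$n_normalized_tokens))
  invisible(x)
}

#' Identify key genes by three-way intersection
#'
#' A key gene must simultaneously be an MCC hub gene, a member of a
#' significant network module, and a meta-hub gene reported by prior
#' studies.
#'
#' @param hub Gene set of hub genes (character vector or tibble).
#' @param module Gene set of hub-module genes.
#' @param meta Gene set of meta-hub genes (or a `meta_hub_set`).
#' @return A `kg_report` list: `kgs` (sorted symbols), `sizes` (tibble of
#'   the three input sizes), `membership` (tibble: per key gene, the three
#'   membership flags).
#' @export
#' @examples
#' identify_kgs(c("A", "B", "C"), c("B", "C", "D"), c("C", "B", "E"))$kgs
identify_kgs <- function(hub, module, meta) {
  if (inherits(meta, "meta_hub_set")) meta <- meta$genes
  sets <- list(hub = as_gene_tbl(hub)$gene,
               module = as_gene_tbl(module)$gene,
               meta = as_gene_tbl(meta)$gene)
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty)) {
    warnf("empty input set(s): %s; key-gene set is empty",
          paste(empty, collapse = ", "))
    kgs <- character()
  } else {
    kgs <- sort(purrr::reduce(sets, intersect))
  }
  structure(list(
    kgs = kgs,
    sizes = tibble(set = names(sets),
                   size = vapply(sets, length, integer(1))),
    membership = tibble(gene = kgs,
                        in_hub = kgs %in% sets$hub,
                        in_module = kgs %in% sets$module,
                        in_meta = kgs %in% sets$meta)
  ), class = "kg_report")
}

#' @export
print.kg_report <- function(x, ...) {
  cat(sprintf("<kg_report> %d key gene(s): %s\n", length(x$kgs),
              paste(x$kgs, collapse = ", ")))
  cat(sprintf("  inputs: hub %d, module %d, meta %d\n",
              x$sizes$size[1], x$sizes$size[2], x$sizes$size[3]))
  invisible(x)
}

#' @rdname identify_kgs
#' @param x A `kg_report`.
#' @param ... Unused.
#' @export
tidy.kg_report <- function(x, ...) x$membership

#' @rdname identify_kgs
#' @export
glance.kg_report <- function(x, ...) {
  tibble(n_kgs = length(x$kgs),
         n_hub = x$sizes$size[x$sizes$set == "hub"],
         n_module = x$sizes$size[x$sizes$set == "module"],
         n_meta = x$sizes$size[x$sizes$set == "meta"])
}
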