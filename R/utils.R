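#' Derive an independent RNG stream seed from a master seed
#'
#' Every randomised artifact (a platform universe, one expression dataset, the
#' PPI edge list, ...) draws from its own stream so that artifacts are
#' independent and reproducible regardless of generation order. The stream
#' seed is `(master_seed * 31 + H(label)) mod (2^31 - 1)` where `H` is the
#' polynomial string hash `H(s) = sum_i code(s_i) * 31^(n-i) mod (2^31 - 1)`
#' over the UTF-8 codes of the concatenated label parts (joined by `"/"`).
#'
#' @param seed Integer master seed.
#' @param ... Label parts (artifact name, platform id, replicate id, ...);
#'   coerced to character and joined with `"/"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "expr", 2, 1)
stream_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer((as.numeric(seed) * 31 + h) %% m)
}

# Run code under a local, derived RNG stream without touching the caller's RNG.
with_stream <- function(seed, ..., code) {
  withr::with_seed(stream_seed(seed, ...), code)
}

#' Normalize gene symbols
#'
#' Uppercases, trims surrounding whitespace, and drops empty strings and
#' duplicates. All set algebra in crosskey is performed on symbols passed
#' through this function, so case variants collapse to one symbol.
#'
#' @param genes Character vector of gene symbols.
#' @return Sorted character vector of unique normalized symbols.
#' @export
normalize_symbols <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  sort(unique(g[!is.na(g) & nzchar(g)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
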