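#' Preprocess a raw expression matrix
#'
#' Detects the measurement scale (values with a maximum above 100 are taken
#' to be linear intensities and replaced by `log2(x + 1)`), then quantile
#' normalizes: within each sample, the value of rank r is replaced by the
#' across-sample mean of the r-th order statistic; tied values receive the
#' average of the quantile means they span.
#'
#' @param raw Numeric probe x sample matrix.
#' @param log2_transform `"auto"` (default, max > 100 triggers the log),
#'   `"always"`, or `"never"`.
#' @return Normalized matrix of the same shape, log2 scale.
#' @export
#' @examples
#' m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
#' rownames(m) <- c("p1", "p2")
#' preprocess_expression(m) # both columns become (2, 3)
preprocess_expression <- function(raw,
                                  log2_transform = c("auto", "always", "never")) {
  log2_transform <- match.arg(log2_transform)
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) {
    bad <- which(!vapply(seq_len(ncol(raw)), function(j)
      is.numeric(raw[, j]), logical(1)))
    stopf("non-numeric expression values in sample column(s): %s",
          paste(colnames(raw)[bad] %||% bad, collapse = ", "))
  }
  if (anyNA(raw)) {
    idx <- which(is.na(raw), arr.ind = TRUE)[1, ]
    stopf("missing expression value at probe '%s', sample '%s'",
          rownames(raw)[idx[1]] %||% idx[1], colnames(raw)[idx[2]] %||% idx[2])
  }
  do_log <- switch(log2_transform,
                   auto = max(raw) > 100,
                   always = TRUE,
                   never = FALSE)
  if (do_log) {
    if (min(raw) < 0) stopf("negative values on a linear intensity scale")
    raw <- log2(raw + 1)
  }
  out <- limma::normalizeQuantiles(raw, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  out
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per probe, computes the log2 fold change (case mean minus control mean)
#' and a moderated t-statistic in which the pooled residual variance
#' \eqn{s_g^2} (with \eqn{d_g = n - 2} df) is shrunk toward a prior variance:
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}. The prior
#' degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2} are estimated
#' by matching the first two moments of \eqn{\log s_g^2} to a scaled F
#' distribution (the standard closed-form moment estimator; \eqn{d_0} may be
#' infinite when the moment equation has no finite solution). Two-sided
#' p-values come from a Student t with \eqn{d_0 + d_g} degrees of freedom.
#'
#' @param ds An [expression_dataset()], or a numeric probe x sample matrix
#'   (then `groups` must be given).
#' @param groups Per-sample `"case"`/`"control"` labels when `ds` is a bare
#'   matrix.
#' @param prior Optional list with fixed hyperparameters `d0`, `s0_sq`,
#'   bypassing estimation (useful for worked examples and sensitivity
#'   checks).
#' @return A `crosskey_ebfit` object: use [tidy()] for the per-probe table
#'   (`probe`, `log2fc`, `t_mod`, `df_total`, `p`, `adj_p`) and [glance()]
#'   for the hyperparameters.
#' @export
#' @examples
#' m <- rbind(g1 = c(0, 2, 3, 5))
#' colnames(m) <- paste0("s", 1:4)
#' fit <- moderated_t_test(m, groups = c("case", "case", "control", "control"),
#'                         prior = list(d0 = 4, s0_sq = 1))
#' tidy(fit)$t_mod # -2.598: shrunken variance (4*1 + 2*2)/6 = 4/3
moderated_t_test <- function(ds, groups = NULL, prior = NULL) {
  if (inherits(ds, "crosskey_dataset")) {
    values <- ds$values
    groups <- ds$groups
  } else {
    values <- as.matrix(ds)
    if (is.null(groups)) stopf("groups required when ds is a matrix")
  }
  case <- values[, groups == "case", drop = FALSE]
  ctrl <- values[, groups == "control", drop = FALSE]
  n1 <- ncol(case); n0 <- ncol(ctrl)
  if (n1 < 2 || n0 < 2) stopf("need at least 2 samples per group")
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  s2 <- (apply(case, 1, var) * (n1 - 1) + apply(ctrl, 1, var) * (n0 - 1)) /
    (n1 + n0 - 2)
  dg <- n1 + n0 - 2
  if (is.null(prior)) {
    if (all(s2 <= .Machine$double.eps)) {
      stopf("all probes have zero within-group variance; cannot estimate hyperparameters")
    }
    fd <- limma::fitFDist(s2, df1 = dg)
    d0 <- fd$df2
    s0_sq <- fd$scale
  } else {
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  }
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  } else {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  }
  t_mod <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n0))
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  structure(list(
    table = tibble(probe = rownames(values) %||% as.character(seq_along(log2fc)),
                   log2fc = as.numeric(log2fc), t_mod = as.numeric(t_mod),
                   df_total = df_total, p = as.numeric(p),
                   adj_p = bh_adjust(as.numeric(p))),
    d0 = d0, s0_sq = s0_sq, n_case = n1, n_control = n0
  ), class = "crosskey_ebfit")
}

#' @export
print.crosskey_ebfit <- function(x, ...) {
  cat(sprintf("<crosskey_ebfit> %d probes, %d case / %d control; d0 = %s, s0^2 = %.4g\n",
              nrow(x$table), x$n_case, x$n_control,
              if (is.finite(x$d0)) sprintf("%.3f", x$d0) else "Inf", x$s0_sq))
  invisible(x)
}

#' @rdname moderated_t_test
#' @param x A `crosskey_ebfit` object.
#' @param ... Unused.
#' @export
tidy.crosskey_ebfit <- function(x, ...) x$table

#' @rdname moderated_t_test
#' @export
glance.crosskey_ebfit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, n_case = x$n_case,
         n_control = x$n_control, n_probes = nrow(x$table))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p-value becomes
#' `min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Collapse probe-level results to gene level
#'
#' Drops probes with blank symbols, then keeps, for every symbol measured by
#' several probes, the record of the probe with the smallest adjusted
#' p-value; exact ties go to the lexicographically smallest probe id. The
#' kept probe's expression row also represents the gene downstream.
#'
#' @param results Tibble of per-probe results (from
#'   `tidy(moderated_t_test(...))`); must carry `probe` and `adj_p`.
#' @param annotation Data frame with columns `probe`, `symbol`.
#' @return The input records, one row per gene, with a `gene` column.
#' @export
collapse_probes <- function(results, annotation) {
  annotation <- as_tibble(annotation)
  stopifnot(all(c("probe", "symbol") %in% names(annotation)))
  results %>%
    left_join(annotation, by = "probe") %>%
    mutate(gene = toupper(trimws(.data$symbol))) %>%
    filter(!is.na(.data$gene), nzchar(.data$gene)) %>%
    arrange(.data$gene, .data$adj_p, .data$probe) %>%
    group_by(.data$gene) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"symbol")
}

#' Threshold gene-level records into a DEG set
#'
#' A gene is called differentially expressed when its absolute log2 fold
#' change is at least `fc_threshold` and its adjusted p-value is strictly
#' below `p_threshold`.
#'
#' @param records Tibble with `gene`, `log2fc`, `adj_p`.
#' @param fc_threshold Minimum |log2FC| (inclusive).
#' @param p_threshold Adjusted-p cutoff (exclusive).
#' @return Tibble `gene`, `direction` (`"up"`/`"down"`) of the DEGs.
#' @export
filter_degs <- function(records, fc_threshold = 1.2, p_threshold = 0.01) {
  records %>%
    filter(abs(.data$log2fc) >= fc_threshold, .data$adj_p < p_threshold) %>%
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) %>%
    select("gene", "direction") %>%
    arrange(.data$gene)
}

#' Run the per-dataset differential-expression stage
#'
#' Preprocessing (scale detection + quantile normalization), the moderated
#' t-test, BH adjustment, probe collapsing, and DEG thresholding in one call.
#'
#' @param ds An [expression_dataset()] with annotation (or pass
#'   `annotation`).
#' @param annotation Probe-to-symbol table; defaults to `ds$annotation`.
#' @param fc_threshold,p_threshold DEG thresholds, see [filter_degs()].
#' @param log2_transform Passed to [preprocess_expression()].
#' @param prior Optional fixed hyperparameters, see [moderated_t_test()].
#' @return Tibble: one row per gene with `gene`, `probe`, `log2fc`, `t_mod`,
#'   `df_total`, `p`, `adj_p`, `is_deg`, `direction`.
#' @export
run_deg <- function(ds, annotation = NULL, fc_threshold = 1.2,
                    p_threshold = 0.01, log2_transform = "auto",
                    prior = NULL) {
  annotation <- annotation %||% ds$annotation
  if (is.null(annotation)) stopf("probe annotation required")
  norm <- preprocess_expression(ds$values, log2_transform)
  fit <- moderated_t_test(norm, groups = ds$groups, prior = prior)
  collapse_probes(tidy(fit), annotation) %>%
    mutate(is_deg = abs(.data$log2fc) >= fc_threshold &
             .data$adj_p < p_threshold,
           direction = ifelse(.data$log2fc > 0, "up", "down")) %>%
    select("gene", "probe", "log2fc", "t_mod", "df_total", "p", "adj_p",
           "is_deg", "direction")
}
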