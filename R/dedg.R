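#' Settings for the per-gene SVM discriminative filter
#'
#' Each candidate gene is scored by a single-feature support-vector machine
#' with an RBF kernel: on a stratified 80% training split, cost and gamma
#' are grid-searched to maximize stratified 5-fold cross-validated accuracy,
#' and that best CV accuracy is the gene's score in the dataset. Scores are
#' averaged over the datasets containing the gene and thresholded strictly
#' (mean accuracy > `accuracy_threshold` selects the gene).
#'
#' @param c_grid Candidate SVM cost values.
#' @param gamma_grid Candidate RBF gamma values.
#' @param cv_folds Cross-validation folds.
#' @param train_fraction Fraction of samples in the training split.
#' @param accuracy_threshold Strict selection threshold on mean accuracy.
#' @param seed Seed; per-gene fold assignments are derived from
#'   `(seed, gene symbol)` and from sample ids (not positions), so results
#'   do not depend on evaluation or sample order.
#' @return An `svm_settings` list.
#' @export
svm_settings <- function(c_grid = c(0.1, 1, 10, 100),
                         gamma_grid = c(0.001, 0.01, 0.1, 1),
                         cv_folds = 5,
                         train_fraction = 0.8,
                         accuracy_threshold = 0.95,
                         seed = 1) {
  stopifnot(length(c_grid) > 0, length(gamma_grid) > 0,
            all(c_grid > 0), all(gamma_grid > 0),
            train_fraction > 0, train_fraction < 1)
  structure(list(c_grid = c_grid, gamma_grid = gamma_grid,
                 cv_folds = cv_folds, train_fraction = train_fraction,
                 accuracy_threshold = accuracy_threshold, seed = seed),
            class = "svm_settings")
}

# Stratified assignment of indices to `k` groups, seeded; `sizes` may instead
# request a two-way split by fraction.
stratified_split <- function(groups, train_fraction, seed) {
  idx <- seq_along(groups)
  train <- integer()
  withr::with_seed(seed, {
    for (g in unique(groups)) {
      ig <- idx[groups == g]
      n_tr <- round(train_fraction * length(ig))
      train <- c(train, sample(ig, n_tr))
    }
  })
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Stratified train/test split of an expression dataset
#'
#' @param ds An [expression_dataset()].
#' @param settings An [svm_settings()].
#' @return List with integer sample indices `train` and `test`.
#' @export
split_train_test <- function(ds, settings = svm_settings()) {
  sp <- stratified_split(ds$groups, settings$train_fraction,
                         stream_seed(settings$seed, "split", ds$name %||% ""))
  counts <- table(factor(ds$groups[sp$train], c("case", "control")))
  if (any(counts < 5)) {
    stopf("fewer than 5 training samples in a group (%s)",
          paste(counts, collapse = "/"))
  }
  sp
}

svm_fold_accuracy <- function(x, y, folds, cost, gamma) {
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    mu <- mean(x[tr]); sdv <- sd(x[tr])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    xs <- (x - mu) / sdv
    fit <- e1071::svm(x = matrix(xs[tr], ncol = 1), y = y[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pred <- predict(fit, matrix(xs[!tr], ncol = 1))
    mean(pred == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Cross-validated SVM accuracy of a single gene
#'
#' @param gene Gene symbol (keys the RNG stream).
#' @param ds A gene-level [expression_dataset()] whose rownames are gene
#'   symbols (see [gene_level_dataset()]).
#' @param settings An [svm_settings()].
#' @return Best 5-fold CV accuracy on the training split (numeric in
#'   `[0, 1]`), with attributes `holdout_accuracy`, `cost`, `gamma`. `NA`
#'   when the gene is absent from the dataset.
#' @export
evaluate_gene_accuracy <- function(gene, ds, settings = svm_settings()) {
  if (!gene %in% rownames(ds$values)) return(NA_real_)
  # Order by sample id so the result is invariant to column permutations.
  ord <- order(colnames(ds$values))
  x <- as.numeric(ds$values[gene, ord])
  y <- factor(ds$groups[ord], levels = c("case", "control"))
  seed_g <- stream_seed(settings$seed, "svm", ds$name %||% "", gene)
  sp <- stratified_split(as.character(y), settings$train_fraction, seed_g)
  xtr <- x[sp$train]; ytr <- y[sp$train]
  folds <- integer(length(ytr))
  withr::with_seed(stream_seed(seed_g, "folds"), {
    for (g in levels(ytr)) {
      ig <- which(ytr == g)
      folds[ig] <- sample(rep_len(seq_len(settings$cv_folds), length(ig)))
    }
  })
  grid <- expand.grid(cost = settings$c_grid, gamma = settings$gamma_grid)
  cv <- mapply(function(cost, gamma) svm_fold_accuracy(xtr, ytr, folds, cost, gamma),
               grid$cost, grid$gamma)
  best <- which.max(cv)
  # Hold-out accuracy of the best model, logged but unused for selection.
  mu <- mean(xtr); sdv <- sd(xtr); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  fit <- e1071::svm(x = matrix((xtr - mu) / sdv, ncol = 1), y = ytr,
                    kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE)
  pred <- predict(fit, matrix((x[sp$test] - mu) / sdv, ncol = 1))
  structure(as.numeric(cv[best]),
            holdout_accuracy = mean(pred == y[sp$test]),
            cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Reduce a probe-level dataset to gene level
#'
#' Uses the probe chosen per gene by [collapse_probes()] (minimum adjusted
#' p-value) as the gene's expression row.
#'
#' @param ds An [expression_dataset()].
#' @param collapsed Gene-level table carrying `gene` and `probe` columns
#'   (e.g. from [run_deg()]).
#' @return An [expression_dataset()] whose rownames are gene symbols.
#' @export
gene_level_dataset <- function(ds, collapsed) {
  vals <- ds$values[collapsed$probe, , drop = FALSE]
  rownames(vals) <- collapsed$gene
  expression_dataset(vals, ds$groups, platform = ds$platform,
                     name = ds$name %||% "dataset")
}

#' Score and select discriminative genes (DEDGs)
#'
#' Evaluates every candidate gene in every dataset containing it, averages
#' the per-dataset CV accuracies, sorts descending (ties: more datasets
#' first, then symbol), and selects genes whose mean accuracy strictly
#' exceeds the threshold.
#'
#' @param datasets Named list of gene-level [expression_dataset()]s.
#' @param genes Candidate gene symbols (typically the gcDEG set).
#' @param settings An [svm_settings()].
#' @return Tibble: `gene`, `n_datasets`, `mean_accuracy`, `selected`, plus
#'   one `acc_<dataset>` column per dataset (NA where absent).
#' @export
select_dedgs <- function(datasets, genes, settings = svm_settings()) {
  genes <- normalize_symbols(genes)
  acc <- purrr::map(datasets, function(ds) {
    vapply(genes, function(g) as.numeric(evaluate_gene_accuracy(g, ds, settings)),
           numeric(1))
  })
  acc_mat <- do.call(cbind, acc)
  colnames(acc_mat) <- paste0("acc_", names(datasets))
  out <- tibble(gene = genes,
                n_datasets = as.integer(unname(rowSums(!is.na(acc_mat)))),
                mean_accuracy = unname(rowMeans(acc_mat, na.rm = TRUE))) %>%
    bind_cols(as_tibble(acc_mat)) %>%
    filter(.data$n_datasets >= 1) %>%
    mutate(selected = .data$mean_accuracy > settings$accuracy_threshold) %>%
    arrange(desc(.data$mean_accuracy), desc(.data$n_datasets), .data$gene)
  out
}
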