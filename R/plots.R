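#' Volcano plot of a differential-expression table
#'
#' @param deg_table Tibble from [run_deg()] (needs `log2fc`, `adj_p`).
#' @param fc_threshold,p_threshold Thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg_table, fc_threshold = 1.2, p_threshold = 0.01) {
  deg_table <- deg_table %>%
    mutate(status = dplyr::case_when(
      .data$adj_p < p_threshold & .data$log2fc >= fc_threshold ~ "up",
      .data$adj_p < p_threshold & .data$log2fc <= -fc_threshold ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(.data$log2fc, -log10(.data$adj_p),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "dodgerblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy profile of the SVM discriminative filter
#'
#' Genes ranked by mean cross-validated accuracy, with the selection
#' threshold marked.
#'
#' @param dedg_table Tibble from [select_dedgs()].
#' @param threshold Selection threshold line.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(dedg_table, threshold = 0.95) {
  dedg_table <- mutate(dedg_table, rank = row_number())
  ggplot2::ggplot(dedg_table,
                  ggplot2::aes(.data$rank, .data$mean_accuracy,
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "gene rank", y = "mean CV accuracy",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for median-split risk groups
#'
#' @param time,event Follow-up times and event indicators.
#' @param expression Per-sample expression of one gene (split at the
#'   median), or an already-made grouping factor.
#' @param gene Label for the plot title.
#' @return A ggplot object.
#' @export
plot_km <- function(time, event, expression, gene = NULL) {
  group <- if (is.numeric(expression)) median_split(expression)
           else factor(expression)
  km <- km_estimate(time, event, group)
  # prepend S(0) = 1 per group for a complete step curve
  km0 <- km %>% distinct(.data$group) %>%
    mutate(time = 0, n_risk = NA_real_, n_event = 0, surv = 1)
  ggplot2::ggplot(bind_rows(km0, km),
                  ggplot2::aes(.data$time, .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(low = "forestgreen",
                                            high = "firebrick")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "risk group", title = gene) +
    ggplot2::theme_minimal()
}
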