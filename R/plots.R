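# ggplot2 helpers for the main result types.

#' Plot estimated activity against the active call
#'
#' Scatter of log2 transcription rate against the robust z-score, colored by
#' the FDR call, with controls marked.
#'
#' @param activity A [call_active()] result.
#' @return A ggplot object.
#' @export
plot_activity <- function(activity) {
  stopifnot(all(c("log2_alpha", "z", "active") %in% names(activity)))
  ggplot2::ggplot(activity,
                  ggplot2::aes(x = .data$log2_alpha, y = .data$z,
                               color = .data$active)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "log2 transcription rate (alpha)",
                  y = "robust z-score", color = "active (FDR)") +
    ggplot2::theme_minimal()
}

#' Heatmap of within-dataset feature ranks across datasets
#'
#' @param ranking A [comprehensive_rank()] result.
#' @param top_n Show only the best `top_n` features.
#' @return A ggplot object.
#' @export
plot_rank_heatmap <- function(ranking, top_n = 30) {
  rank_cols <- grep("^rank_", names(ranking), value = TRUE)
  df <- head(ranking, top_n) |>
    tidyr::pivot_longer(dplyr::all_of(rank_cols), names_to = "dataset",
                        values_to = "rank") |>
    dplyr::mutate(dataset = sub("^rank_", "", .data$dataset))
  df$feature <- factor(df$feature, levels = rev(head(ranking$feature, top_n)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$feature,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "within-dataset\nrank") +
    ggplot2::theme_minimal()
}

#' Cumulative hardness distributions per region category
#'
#' @param hardness_table Tibble with `hardness` and `category`.
#' @return A ggplot object.
#' @export
plot_hardness_ecdf <- function(hardness_table) {
  ggplot2::ggplot(hardness_table,
                  ggplot2::aes(x = .data$hardness, color = .data$category)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "hardness (rank-normalized |label - probability|)",
                  y = "cumulative fraction of regions", color = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-wise evaluation statistics with mean and spread
#'
#' @param x An `mpra_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_eval
#' @export
autoplot.mpra_eval <- function(x, ...) {
  ggplot2::ggplot(x$folds, ggplot2::aes(x = .data$test, y = .data$statistic)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "red",
                          size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-fold statistic") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
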