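#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_hline labs theme_minimal facet_wrap coord_flip
#' @export
ggplot2::autoplot

#' Fitness trajectory of a GA run
#'
#' Best and mean population fitness per generation.
#'
#' @param object A `ga_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ga_run <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean"),
                           names_to = "statistic", values_to = "fitness")
  ggplot(h, aes(x = .data$generation, y = .data$fitness,
                color = .data$statistic)) +
    geom_line() +
    labs(x = "generation", y = "macro F1 fitness", color = NULL,
         title = sprintf("GA run (seed %s)", format(object$seed))) +
    theme_minimal()
}

#' Feature-selection frequency bar plot
#'
#' Selection frequency of each feature across GA runs, with the reporting
#' threshold marked; features at or above it are highlighted.
#'
#' @param frequency Output of [aggregate_runs()].
#' @param threshold Threshold line, percent.
#' @param top_n Show only the `top_n` most frequent features (`NULL` = all).
#' @return A ggplot.
#' @export
plot_feature_frequency <- function(frequency, threshold = 50, top_n = 30) {
  d <- dplyr::arrange(frequency, dplyr::desc(.data$frequency))
  if (!is.null(top_n)) d <- head(d, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$frequency,
                fill = .data$frequency >= threshold)) +
    geom_col(show.legend = FALSE) +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "selection frequency (% of runs)") +
    theme_minimal()
}

#' Per-fold metric plot for a model comparison
#'
#' One panel per metric, per-fold points and lines per model, for the CV
#' rows of a [run_comparison()] table.
#'
#' @param results Output of [run_comparison()].
#' @param level Metric level to plot.
#' @return A ggplot.
#' @export
plot_fold_metrics <- function(results, level = "patient") {
  d <- dplyr::filter(results, .data$scheme == "cv", .data$level == !!level)
  d <- tidyr::pivot_longer(d, c("accuracy", "f1_macro", "precision", "recall"),
                           names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$fold, y = .data$value, color = .data$model)) +
    geom_line() + geom_point() +
    facet_wrap(~metric) +
    labs(x = "CV fold", y = NULL, color = NULL) +
    theme_minimal()
}
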