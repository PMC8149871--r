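# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of the threshold landscape
#'
#' Shows, for every (lo, hi) cutoff pair, the smaller of the two
#' per-class accuracies (fill) so the abstention trade-off surface is
#' visible at a glance.
#'
#' @param object A `threshold_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_landscape <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    min_accuracy = pmin(.data$acc_severe, .data$acc_mild_moderate)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lo, .data$hi,
                                   fill = .data$min_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "lower cutoff", y = "upper cutoff",
                  fill = "min class\naccuracy",
                  title = "Gray-zone threshold landscape") +
    ggplot2::theme_minimal()
}

#' Accuracy-coverage trade-off plot
#'
#' Each point is a cutoff pair; per-class accuracies against the
#' fraction of instances still classified.
#'
#' @param landscape A `threshold_landscape`.
#' @return A ggplot.
#' @export
plot_accuracy_coverage <- function(landscape) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(landscape),
    c("acc_severe", "acc_mild_moderate"),
    names_to = "class", values_to = "accuracy"
  )
  df$class <- sub("^acc_", "", df$class)
  ggplot2::ggplot(df, ggplot2::aes(.data$coverage, .data$accuracy,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "coverage (fraction classified)",
                  y = "per-class accuracy") +
    ggplot2::theme_minimal()
}

#' Saturation-scan heatmap
#'
#' Severity Score of every substitution, position by mutant residue.
#'
#' @param object A `saturation_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$resno, .data$mut_aa,
                               fill = .data$severity_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "structure position", y = "mutant residue",
                  fill = "Severity\nScore",
                  title = "Saturation mutagenesis scan") +
    ggplot2::theme_minimal()
}

#' Severity Score distributions per class
#'
#' Boxplots of predicted scores by true class label, the standard
#' check that the ensemble separates the phenotypes.
#'
#' @param scores Numeric Severity Scores.
#' @param labels Class labels.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores, labels) {
  df <- tibble::tibble(score = scores, label = as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$score,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Severity Score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
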