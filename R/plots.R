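#' Plot an ROC curve
#'
#' Stepped ROC curve with the no-discrimination diagonal for reference and
#' the AUC in the subtitle.
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::geom_point(size = 1, colour = "#2c7fb8") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Hidden-relationship discovery ROC",
      subtitle = sprintf("AUC = %.3f (%d TP, %d FP)",
        object$auc, object$n_tp, object$n_fp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the R-scaled score distribution of a co-publication table
#'
#' Histogram of R-scaled scores with the biological-significance cutoff
#' marked.
#'
#' @param object A `copub_scores` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot copub_scores
#' @export
autoplot.copub_scores <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$R_scaled)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2c7fb8", colour = "white") +
    ggplot2::geom_vline(xintercept = object$significance_cutoff,
      linetype = "dashed", colour = "#d95f02") +
    ggplot2::labs(
      x = "R-scaled score", y = "Concept pairs",
      title = "Co-publication score distribution",
      subtitle = sprintf("dashed line: significance cutoff %g",
        object$significance_cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot inferred scores of labeled candidate pairs
#'
#' Dot plot of the inferred relationship score by validation label,
#' optionally with a chosen score cutoff marked.
#'
#' @param labeled Labeled pairs from [label_pairs()].
#' @param cutoff Optional score cutoff to draw.
#' @return A ggplot object.
#' @export
plot_ri_by_label <- function(labeled, cutoff = NULL) {
  p <- ggplot2::ggplot(labeled, ggplot2::aes(x = .data$label, y = .data$ri)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5,
      colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Test-set label", y = "Inferred R-scaled score",
      title = "Inferred scores of candidate hidden pairs"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
      colour = "#d95f02")
  }
  p
}
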