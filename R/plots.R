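# ggplot2 display methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a residue-level ROC curve
#'
#' @param object A `roc_result` from [residue_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$roc[order(object$roc$fpr, object$roc$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Residue-level ROC over vote thresholds",
      subtitle = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-protein vote distributions from cross-validation
#'
#' @param object A `loocv_result` from [loocv_patch_classification()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_result <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth,
                                   y = .data$votes / .data$total,
                                   colour = .data$predicted)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "True patch class", y = "Vote fraction v / |T|",
                  colour = "Predicted",
                  title = "Leave-one-out patch classification") +
    ggplot2::theme_minimal()
}

#' Plot the top-k coverage/accuracy trade-off
#'
#' @param tradeoff Tibble from [topk_coverage_accuracy()] evaluated at
#'   several `k` (optionally row-bound over proteins).
#' @return A ggplot object.
#' @export
plot_coverage_accuracy <- function(tradeoff) {
  df <- tradeoff |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(coverage = mean(.data$coverage),
                     accuracy = mean(.data$accuracy), .groups = "drop") |>
    tidyr::pivot_longer(c("coverage", "accuracy"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$k)) +
    ggplot2::labs(x = "Top-ranking patches merged (k)", y = "Fraction",
                  colour = NULL,
                  title = "Coverage/accuracy trade-off") +
    ggplot2::theme_minimal()
}
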