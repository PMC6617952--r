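# Plot methods for the calibration and ROC result types.

#' Plot an undiagnosed-rate line fit
#'
#' Shows the per-bin rates against bin midpoints with both fitted lines:
#' the free-intercept OLS line and the zero-intercept line used downstream.
#'
#' @param object A `rate_line_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_line_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(intercept = 0, slope = object$slope_zero,
                         colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "risk-score bin midpoint",
                  y = "undiagnosed-dementia rate",
                  title = sprintf("y = %.3f x (zero intercept); dashed: free intercept",
                                  object$slope_zero)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `silverphen_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silverphen_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$spe, y = .data$sen)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Risk-score distribution by group
#'
#' Overlaid score histograms for cases and controls; with a well-separated
#' model, case scores stochastically dominate control scores.
#'
#' @param scores Score tibble from [predict_risk_scores()] with a `group`
#'   column.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 30) {
  stopifnot("group" %in% names(scores))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "risk score", y = "subjects") +
    ggplot2::theme_minimal()
}
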