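#' Plot a threshold-sweep ROC curve
#'
#' Sensitivity against 1 - specificity (FP/(TN+FP)) for varying retention
#' thresholds; the point with the highest F-measure is highlighted.
#'
#' @param object A [roc_over_threshold()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kdvs_roc <- function(object, ...) {
  best <- dplyr::filter(object, .data$best)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$one_minus_specificity, y = .data$sensitivity
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = best, colour = "red", size = 2.5) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity (FP / (TN + FP))", y = "sensitivity",
      title = "Term retention ROC over the error threshold",
      subtitle = sprintf(
        "best F-measure %.3f at threshold %.3f",
        best$f_measure[1], best$threshold[1]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-term errors of a knowledge-driven run
#'
#' Mean cross-validated test error of every processed term against its
#' submatrix size, coloured by retention, with the threshold as a
#' horizontal line.
#'
#' @param object A [run_kdvs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kdvs_result <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$status == "processed")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$ps, y = .data$error_mean, colour = .data$retained
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~domain) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey55")) +
    ggplot2::labs(
      x = "term size (probesets)", y = "mean test error",
      colour = "retained",
      title = "Per-term cross-validated error",
      subtitle = sprintf("retention threshold %.1f%%", 100 * object$threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-split test errors of a nested cross-validation run
#'
#' @param object A [nested_cv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$split), y = .data$test_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$error_mean, linetype = "dashed") +
    ggplot2::labs(
      x = "external split", y = "test error",
      title = sprintf("%s + %s nested CV", object$selector, object$classifier),
      subtitle = sprintf(
        "mean %.1f%% +/- %.1f%%", 100 * object$error_mean, 100 * object$error_sd
      )
    ) +
    ggplot2::theme_minimal()
}
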