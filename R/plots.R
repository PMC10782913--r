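#' Kaplan-Meier plot for risk groups
#'
#' Step curves of the product-limit estimate, one per group.
#'
#' @param km Curve tibble from [km_curve()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = "Risk group") +
    ggplot2::theme_minimal()
}

#' ROC curves at survival horizons
#'
#' @param scores Tibble from [risk_score()].
#' @param clinical Clinical tibble.
#' @param horizons Months (default 12, 36, 60).
#' @return A ggplot object with one curve per horizon, annotated
#'   with its IPCW AUC.
#' @export
plot_time_roc <- function(scores, clinical, horizons = c(12, 36, 60)) {
  auc <- time_dependent_auc(scores, clinical, horizons)
  curves <- purrr::map_dfr(horizons, function(h) {
    dplyr::mutate(time_roc_curve(scores, clinical, h), horizon = h)
  })
  curves <- dplyr::left_join(curves, auc, by = "horizon")
  curves$label <- sprintf("%d mo (AUC %.3f)", curves$horizon, curves$auc)
  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$label)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot: predicted versus observed survival
#'
#' @param cal Tibble from [calibration()].
#' @return A ggplot object; points on the diagonal indicate a
#'   well-calibrated model.
#' @export
plot_calibration <- function(cal) {
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted survival", y = "Observed survival (KM)") +
    ggplot2::theme_minimal()
}

#' Reversal-proportion trend across diagnosis groups
#'
#' One line per pair showing the fraction of samples with the
#' regulator at or above its target, across ordered groups (e.g.
#' normal, LGG, GBM).
#'
#' @param prop Tibble from [reversal_proportion()].
#' @return A ggplot object.
#' @export
plot_reversal_trend <- function(prop) {
  ggplot2::ggplot(prop, ggplot2::aes(x = .data$group, y = .data$proportion,
                                     group = .data$pair)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Fraction with regulator ≥ target") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pair_signature <- function(object, ...) {
  df <- tidy(object)
  df$pair <- stats::reorder(df$pair, df$coefficient)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient, y = .data$pair)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Cox coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
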