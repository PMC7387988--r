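#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an energy map
#'
#' Electrodes on the vertical axis, subbands on the horizontal axis, fill by
#' (normalized) log-variance energy — the "image" the networks see.
#'
#' @param object An `energy_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.energy_map <- function(object, ...) {
  df <- as_tibble(object)
  df$band <- sprintf("%g-%g", df$band_lo, df$band_hi)
  df$band <- factor(df$band, levels = unique(df$band))
  df$channel <- factor(df$channel, levels = rev(object$channel_names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$channel,
                                   fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (object$normalized) "z-energy" else "ln var") +
    ggplot2::labs(x = "subband (Hz)", y = "electrode") +
    ggplot2::theme_minimal()
}

#' Training curves of a fit
#'
#' Loss, training accuracy and validation accuracy against iteration, with
#' the selected (best-validation) iteration marked.
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "iteration (full-batch update)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fold accuracies of a cross-validation
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot of per-fold accuracy with the mean as a line.
#' @exportS3Method
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' Bar profile of learned spatial filters
#'
#' One panel per first-layer kernel, weight per electrode — a flat-layout
#' surrogate for scalp topographies, highlighting which channels dominate
#' each learned spatial projection.
#'
#' @param filters Tibble from [extract_spatial_filters()].
#' @return A ggplot.
#' @export
plot_spatial_filters <- function(filters) {
  ggplot2::ggplot(filters,
                  ggplot2::aes(x = .data$channel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~filter, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "electrode index", y = "kernel weight") +
    ggplot2::theme_minimal()
}
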