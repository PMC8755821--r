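#' Plot class-averaged normalised time courses
#'
#' Mean baseline-normalised firing rate per experimental period for the
#' excitatory, inhibitory and nonresponsive classes, with standard-error
#' ribbons.
#'
#' @param timecourse Output of [normalized_timecourse()].
#' @return A ggplot.
#' @export
plot_timecourse <- function(timecourse) {
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(x = .data$period, y = .data$mean_norm_rate,
                               colour = .data$response_class,
                               group = .data$response_class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_norm_rate - .data$sem,
                                          ymax = .data$mean_norm_rate + .data$sem)) +
    ggplot2::scale_colour_manual(values = c(excitatory = "#c0392b",
                                            inhibitory = "#2980b9",
                                            nonresponsive = "#27ae60")) +
    ggplot2::labs(x = "Period", y = "Normalised rate (baseline z-score)",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' @describeIn permutation_analysis Overlaid labelled vs null performance
#'   distributions per grouping, with the permutation p-value annotated.
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.decoding_result <- function(object, ...) {
  labs <- object$summary |>
    dplyr::mutate(lab = sprintf("p = %.2g ± %.1g", .data$p_value, .data$p_error))
  ggplot2::ggplot(object$performance,
                  ggplot2::aes(x = .data$auc, fill = .data$condition)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_text(data = labs, inherit.aes = FALSE, x = -Inf, y = Inf,
                       hjust = -0.05, vjust = 1.5, size = 3,
                       ggplot2::aes(label = .data$lab)) +
    ggplot2::facet_wrap(~grouping) +
    ggplot2::scale_fill_manual(values = c(labelled = "grey30", null = "white"),
                               labels = c(labelled = "labelled", null = "no information")) +
    ggplot2::labs(x = "One-vs-rest ROC performance", y = "Resamples", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stimulus image
#'
#' @param x A [stim_image()].
#' @param ... Unused.
#' @return A ggplot rendering the intensity matrix in grayscale.
#' @export
plot_stimulus <- function(x, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    intensity = as.vector(unclass(x))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Plot energy-weighted spectral averages of an image set
#'
#' Reproduces the horizontal-vs-vertical spectral-centroid scatter that
#' separates scrambled from intact images.
#'
#' @param summary Output of [spectral_summary()].
#' @return A ggplot.
#' @export
plot_spectral_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$ewsa_h, y = .data$ewsa_v,
                                        colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Horizontal spectral average (cycles/image)",
                  y = "Vertical spectral average (cycles/image)",
                  colour = "Grouping") +
    ggplot2::theme_minimal()
}
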