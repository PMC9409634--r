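#' Plot a hierarchical partitioning result
#'
#' Bar chart of each predictor's independent and joint contribution to the
#' combined-model R^2, ordered by independent contribution.
#'
#' @param object A `"hier_partition"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hier_partition <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("independent", "joint"),
                        names_to = "component", values_to = "contribution") |>
    dplyr::mutate(predictor = stats::reorder(.data$predictor,
                                             .data$contribution,
                                             FUN = max))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor,
                                  y = 100 * .data$contribution,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of outcome variance",
                  title = paste("Partitioning of R² for",
                                object$response),
                  subtitle = sprintf("combined-model R² = %.3f (n = %d)",
                                     object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a Welch tachogram spectrum
#'
#' PSD with the LF (0.04--0.15 Hz) and HF (0.15--0.4 Hz) bands shaded.
#'
#' @param object An `"hrv_spectrum"` tibble (attribute `spectrum` of
#'   [hrv_spectral()] output).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hrv_spectrum <- function(object, ...) {
  bands <- tibble(band = c("LF", "HF"), lo = c(0.04, 0.15),
                  hi = c(0.15, 0.4))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    fill = .data$band),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 0.5)) +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (ms²/Hz)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot supine and standing tachograms for one subject
#'
#' @param df Long beat table with `posture`, `beat`, `interval_ms` (one
#'   subject, e.g. one [simulate_posture_pair()] draw).
#' @return A ggplot object.
#' @export
plot_posture_pair <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beat, y = .data$interval_ms)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~posture, ncol = 1) +
    ggplot2::labs(x = "beat", y = "NN interval (ms)") +
    ggplot2::theme_minimal()
}
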