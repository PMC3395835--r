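#' Plot an acceleration window
#'
#' Per-axis traces plus the magnitude signal over the 5-second window.
#'
#' @param object An `accel_window`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accel_window
#' @export
autoplot.accel_window <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("ax_g", "ay_g", "az_g"),
                            names_to = "axis", values_to = "accel_g")
  mag <- tibble(time_s = object$time_s, axis = "|a|",
                accel_g = magnitude_signal(object))
  ggplot2::ggplot(bind_rows(df, mag),
                  ggplot2::aes(x = .data$time_s, y = .data$accel_g,
                               colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the swarm fitness trace of a clustering fit
#'
#' Best-so-far quantization error against iteration; regroup episodes show
#' up as renewed descent after plateaus.
#'
#' @param object A `regpso_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regpso_fit
#' @export
autoplot.regpso_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$trace) - 1L,
               fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "quantization error f(g(t))") +
    ggplot2::theme_minimal()
}

#' Plot a per-stratum evaluation table
#'
#' Dodged bar chart of sensitivity / specificity per stratum for each
#' classifier, from [evaluate_fall_detector()] output.
#'
#' @param metrics Tibble with `classifier`, `stratum`, `metric`, `value`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$stratum, y = .data$value,
                               fill = .data$classifier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
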