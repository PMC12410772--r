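# ggplot2 graphics for waveforms, impulse-speed fits and experiment
# results.

#' Plot a predicted AP-GRF waveform against the measured one
#'
#' @param predicted Predicted waveform, %BW.
#' @param truth Optional measured waveform, %BW.
#' @param rate Frame rate, Hz.
#' @param frames Optional frame subset to display.
#' @return A ggplot object.
#' @export
plot_waveform <- function(predicted, truth = NULL, rate = 120,
                          frames = NULL) {
  frames <- frames %||% seq_along(predicted)
  df <- tibble::tibble(time_s = (frames - 1) / rate,
                       value = predicted[frames], series = "predicted")
  if (!is.null(truth)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      time_s = (frames - 1) / rate, value = truth[frames],
      series = "measured"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "AP-GRF (%BW)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.impulse_fit <- function(object, ..., grid = seq(2.05, 4.45, 0.1)) {
  df <- tibble::tibble(speed = grid,
                       impulse = object$intercept + object$slope * grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$speed, y = .data$impulse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "speed (m/s)",
                  y = sprintf("%s (%%BW.s)", sub("_", " ", object$metric))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fit_comparison <- function(object, ...) {
  df <- tibble::tibble(
    speed = rep(object$grid, 2),
    impulse = c(object$reference, object$candidate),
    line = rep(c("reference", "candidate"), each = length(object$grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$speed, y = .data$impulse,
                                   colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "speed (m/s)", y = "impulse (%BW.s)", colour = NULL,
                  subtitle = sprintf("line RMSE %.3f %%BW.s", object$rmse)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-configuration stance RMSE
#'
#' @param results A [run_experiment()] result tibble.
#' @return A ggplot object.
#' @export
plot_results <- function(results) {
  sm <- summarize_results(results)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$configuration,
                                   y = .data$mean_rmse_bw)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rmse_bw - .data$sd_rmse_bw,
      ymax = .data$mean_rmse_bw + .data$sd_rmse_bw), width = 0.2) +
    ggplot2::labs(x = NULL, y = "stance RMSE (%BW)") +
    ggplot2::theme_minimal()
}

#' Impulse points with the fitted speed line
#'
#' @param points Impulse points from [compute_impulses()].
#' @param fit An `impulse_fit` for one metric.
#' @return A ggplot object.
#' @export
plot_impulse_speed <- function(points, fit) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$speed,
                                       y = .data[[fit$metric]])) +
    ggplot2::geom_point(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "speed (m/s)",
                  y = sprintf("%s (%%BW.s)", sub("_", " ", fit$metric))) +
    ggplot2::theme_minimal()
}
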