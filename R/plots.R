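#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, plus a
#' predicted-vs-measured scatter helper:
#'
#' * `autoplot.plsr_model()` — the regression coefficient spectrum against
#'   wavelength, the usual way to see which bands a calibration uses.
#' * `autoplot.press_curve()` — PRESS against factor count, with the selected
#'   factor count marked when available.
#' * `plot_noise_grid()` — noise level against integration count, one line
#'   per exposure time, on log-log axes.
#' * `plot_predictions()` — predicted vs measured SSC for a test set, with
#'   the identity line.
#'
#' @param object A fitted `plsr_model` or a `press_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name specbrix-plots
NULL

#' @rdname specbrix-plots
#' @export
autoplot.plsr_model <- function(object, ...) {
  ggplot2::ggplot(coefficient_spectrum(object),
                  ggplot2::aes(.data$wavelength, .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient",
                  title = "Regression coefficient spectrum")
}

#' @rdname specbrix-plots
#' @export
autoplot.press_curve <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$factors, .data$press)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PLS factors", y = "PRESS (Brix²)",
                  title = "Leave-one-out PRESS")
  if ("selected" %in% names(d)) {
    p <- p + ggplot2::geom_point(data = d[d$selected, ], colour = "red",
                                 size = 3)
  }
  p
}

#' @rdname specbrix-plots
#' @param grid_tbl Output of [noise_grid()].
#' @export
plot_noise_grid <- function(grid_tbl) {
  ggplot2::ggplot(grid_tbl,
                  ggplot2::aes(.data$integrations, .data$nl,
                               colour = factor(.data$exposure_ms),
                               group = .data$exposure_ms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "integrations", y = "noise level (AU)",
                  colour = "exposure (ms)")
}

#' @rdname specbrix-plots
#' @param model A fitted `plsr_model`.
#' @param test A spectral dataset tibble on the model's grid.
#' @export
plot_predictions <- function(model, test) {
  d <- tibble::tibble(measured = test$ssc,
                      predicted = predict(model, test))
  ggplot2::ggplot(d, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "measured SSC (% Brix)", y = "predicted SSC (% Brix)")
}
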