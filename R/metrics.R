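#' Calibration validation metrics
#'
#' The standard scalar metrics used to judge an SSC calibration:
#'
#' * `rmse()` — root mean square error, `sqrt(mean((yhat - y)^2))`, in % Brix.
#' * `r_squared()` — coefficient of determination,
#'   `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; can be negative for
#'   models worse than the mean predictor.
#' * `rpd()` — ratio of performance to deviation, `sd(y) / rmse(y, yhat)`,
#'   with the n-1 sample convention for the standard deviation (set
#'   `sd_population = TRUE` for the 1/n convention). Returns `Inf` when the
#'   RMSE is exactly zero.
#' * `slope_offset_bias()` — ordinary least squares fit of *predicted on
#'   measured* (`yhat ~ slope * y + offset`) plus the mean bias
#'   `mean(yhat - y)`; with this orientation a slope above 1 pairs with a
#'   negative offset around the mean.
#'
#' @param y Measured reference values (% Brix).
#' @param yhat Predicted values, same length.
#' @param sd_population Use the 1/n standard deviation in `rpd()`.
#' @return `rmse()`, `r_squared()`, `rpd()`: a single number.
#'   `slope_offset_bias()`: a one-row tibble with columns `slope`, `offset`,
#'   `bias`.
#' @examples
#' y <- c(8, 9, 10); yhat <- c(8.3, 8.8, 10.5)
#' rmse(y, yhat)
#' r_squared(y, yhat)
#' slope_offset_bias(y, yhat)
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((yhat - y)^2))
}

#' @rdname rmse
#' @export
r_squared <- function(y, yhat) {
  check_pair(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("constant reference values: R2 is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname rmse
#' @export
rpd <- function(y, yhat, sd_population = FALSE) {
  check_pair(y, yhat)
  if (length(y) < 2) abort("rpd needs at least 2 samples")
  e <- rmse(y, yhat)
  s <- if (sd_population) sqrt(mean((y - mean(y))^2)) else sd(y)
  if (e == 0) return(Inf)
  s / e
}

#' @rdname rmse
#' @export
slope_offset_bias <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 2 || var(y) == 0) {
    abort("slope/offset need at least 2 distinct reference values")
  }
  slope <- sum((y - mean(y)) * (yhat - mean(yhat))) / sum((y - mean(y))^2)
  tibble::tibble(
    slope = slope,
    offset = mean(yhat) - slope * mean(y),
    bias = mean(yhat - y)
  )
}

check_pair <- function(y, yhat) {
  if (length(y) == 0) abort("empty input")
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  invisible(NULL)
}

#' Qualitative RPD interpretation band
#'
#' Conventional reading of the ratio of performance to deviation:
#' below 1.5 the model cannot describe the data; 1.5-2.0 discriminates low
#' from high values; 2.0-2.5 allows approximate quantitative prediction;
#' 2.5-3.0 is good and above 3.0 excellent.
#'
#' @param rpd Numeric RPD value(s).
#' @return Character vector of band labels.
#' @export
rpd_class <- function(rpd) {
  cut(rpd,
    breaks = c(-Inf, 1.5, 2, 2.5, 3, Inf),
    labels = c("unusable", "discriminating", "approximate quantitative",
               "good", "excellent"),
    right = FALSE
  ) |> as.character()
}
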