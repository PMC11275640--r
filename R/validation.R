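#' Validate a fitted model on its training and test data
#'
#' Produces the three standard validation contexts of an SSC calibration as
#' one tidy table:
#'
#' * `calibration` — the model's predictions on its own training set;
#' * `cross_validation` — the leave-one-out predictions at the selected
#'   factor count, taken from the model's PRESS curve;
#' * `prediction` — predictions on the held-out test set, including the RPD.
#'
#' Slope, offset and bias (see [slope_offset_bias()]) are reported for every
#' context; the RPD only for prediction, where the reference SD is that of an
#' independent test set. When the prediction R-squared exceeds the calibration
#' R-squared by more than 0.15 a diagnostic message flags the discrepancy
#' (agreement between the three contexts is the usual no-overfitting check);
#' this is a note, never an error.
#'
#' @param model A `plsr_model` fitted by [plsr_train()] (the cross-validation
#'   row requires the attached PRESS curve).
#' @param train,test Spectral dataset tibbles on the model's grid.
#' @return A tibble with one row per context and columns `context`, `n`,
#'   `factors`, `r2`, `rmse`, `rpd`, `slope`, `offset`, `bias`.
#' @export
validate_model <- function(model, train, test) {
  if (is.null(model$press)) {
    abort("model carries no PRESS curve; fit it with plsr_train()")
  }
  h <- model$n_factors
  loo_pred <- attr(model$press, "predictions")[, h]
  y_train <- train$ssc
  if (length(y_train) != length(loo_pred) ||
      any(abs(attr(model$press, "y") - y_train) > 1e-9)) {
    abort("`train` does not match the data the PRESS curve was computed on")
  }
  cal <- context_report("calibration", y_train, predict(model, train), h)
  cv <- context_report("cross_validation", y_train, loo_pred, h)
  pred <- context_report("prediction", test$ssc, predict(model, test), h,
                         with_rpd = TRUE)
  out <- dplyr::bind_rows(cal, cv, pred)
  if (pred$r2 - cal$r2 > 0.15) {
    message(sprintf(
      "note: prediction R2 (%.3f) exceeds calibration R2 (%.3f) by > 0.15; check the split",
      pred$r2, cal$r2
    ))
  }
  out
}

context_report <- function(context, y, yhat, factors, with_rpd = FALSE) {
  sob <- slope_offset_bias(y, yhat)
  tibble::tibble(
    context = context,
    n = length(y),
    factors = factors,
    r2 = r_squared(y, yhat),
    rmse = rmse(y, yhat),
    rpd = if (with_rpd) rpd(y, yhat) else NA_real_,
    slope = sob$slope,
    offset = sob$offset,
    bias = sob$bias
  )
}

#' Apply a model to a foreign test set (calibration transfer)
#'
#' Evaluates a fitted model, without any refitting, on a test set drawn from a
#' different population than it was trained on — e.g. an SSC model built on
#' red-fruit spectra applied to white fruit. The wavelength grids must be
#' identical; a mismatch is an error, guarding against mixing instruments.
#'
#' @param model A `plsr_model`.
#' @param foreign_test A spectral dataset tibble on the model's exact grid.
#' @return A one-row tibble in the same layout as [validate_model()]'s
#'   `prediction` row.
#' @export
transfer_validate <- function(model, foreign_test) {
  yhat <- predict(model, foreign_test)   # grid checked inside
  context_report("prediction", foreign_test$ssc, yhat, model$n_factors,
                 with_rpd = TRUE)
}

#' Regression coefficient spectrum of a fitted model
#'
#' The coefficient vector aligned to the model's (derivative-trimmed)
#' wavelength grid. Peaks locate the wavelengths the calibration actually
#' uses, so comparing coefficient spectra across varieties shows whether a
#' model leans on pigment bands or on sugar/water bands.
#'
#' @param model A fitted `plsr_model`.
#' @return A tibble with columns `wavelength` (nm) and `coefficient`.
#' @export
coefficient_spectrum <- function(model) {
  wl <- model$wavelengths %||% seq_along(model$coefficients)
  tibble::tibble(wavelength = wl, coefficient = model$coefficients)
}
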