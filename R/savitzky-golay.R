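#' Savitzky-Golay second derivative of a spectrum
#'
#' Second-derivative filtering is the standard pre-treatment before
#' calibration here: it removes additive baseline offsets and linear tilts
#' exactly (any polynomial up to the fitting order is reproduced exactly by
#' the filter) and sharpens overlapping absorption bands.
#'
#' The filter is the central row of the Savitzky-Golay least-squares
#' polynomial filter ([signal::sgolay()]). Edge points where the full window
#' does not fit are dropped — the output is shorter than the input by
#' `window - 1` points, `(window - 1)/2` on each side — rather than padded;
#' padding would fabricate data that leaks into calibration.
#'
#' The derivative is computed in index units (AU per grid-point squared) by
#' default. On a uniform grid this differs from a per-nm derivative only by
#' the constant factor `step^2`, which a linear calibration absorbs; set
#' `per_nm = TRUE` to divide by `step^2`.
#'
#' @param y Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @param window Odd integer window size, >= 5. Default 15.
#' @param polyorder Polynomial fitting order, >= 2 and < `window`. Default 2,
#'   the minimal order supporting a second derivative and the usual
#'   chemometrics choice.
#' @param step Grid step in nm, used only when `per_nm = TRUE`.
#' @param per_nm If `TRUE`, scale to AU per nm squared.
#' @return Numeric vector (or matrix) of second-derivative values,
#'   `length(y) - window + 1` points per spectrum.
#' @examples
#' sg_second_derivative((1:31)^2) # exactly 2 everywhere
#' @export
sg_second_derivative <- function(y, window = 15, polyorder = 2,
                                 step = 1, per_nm = FALSE) {
  coefs <- sg_coefficients(window, polyorder)
  vec_in <- !is.matrix(y)
  if (vec_in) y <- matrix(y, nrow = 1)
  p <- ncol(y)
  if (p < window) {
    abort(sprintf("spectrum has %d points but the window needs %d", p, window))
  }
  out_len <- p - window + 1
  out <- matrix(0, nrow(y), out_len)
  for (k in seq_len(window)) {
    out <- out + coefs[k] * y[, k:(k + out_len - 1), drop = FALSE]
  }
  if (per_nm) out <- out / step^2
  if (vec_in) out[1, ] else out
}

# Central-row SG convolution coefficients for the second derivative,
# in index units (a pure quadratic maps to exactly 2).
sg_coefficients <- function(window, polyorder) {
  if (window %% 2 != 1 || window < 5) {
    abort("window must be an odd integer >= 5")
  }
  if (polyorder < 2 || polyorder >= window) {
    abort("polyorder must be >= 2 and < window")
  }
  f <- signal::sgolay(p = polyorder, n = window, m = 2)
  as.numeric(f[(window + 1) / 2, ])
}

#' Second-derivative transform of a spectral dataset
#'
#' Applies [sg_second_derivative()] to every sample row of a spectral dataset
#' and trims the wavelength grid by `(window - 1)/2` points on each side to
#' match. Metadata columns (`sample_id`, `variety`, `ssc`) carry through
#' unchanged.
#'
#' @param data A spectral dataset tibble (see [spectra_matrix()]).
#' @inheritParams sg_second_derivative
#' @return A spectral dataset tibble on the trimmed grid whose spectral values
#'   are second derivatives.
#' @export
derivative_spectra <- function(data, window = 15, polyorder = 2,
                               per_nm = FALSE) {
  validate_spectra(data, min_grid = window)
  wl <- spectra_wavelengths(data)
  x <- spectra_matrix(data)
  half <- (window - 1) / 2
  d2 <- sg_second_derivative(x, window = window, polyorder = polyorder,
                             step = grid_step(wl), per_nm = per_nm)
  as_spectra(d2, wl[(half + 1):(length(wl) - half)],
             ssc = data$ssc, variety = data$variety,
             sample_id = data$sample_id)
}
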