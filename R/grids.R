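#' Instrument wavelength grids
#'
#' Preset wavelength grids (nm) for the two diffuse-reflectance instruments the
#' pipeline targets: a visible/near-infrared spectrophotometer covering
#' 500-978 nm at 2 nm resolution (240 channels) and a near-infrared
#' spectrophotometer covering 908-1676 nm at 6.19 nm resolution (125 channels).
#'
#' @return Numeric vector of wavelengths in nm, strictly increasing with a
#'   uniform step.
#' @examples
#' length(grid_visnir()) # 240
#' range(grid_nir())
#' @export
grid_visnir <- function() seq(500, 978, by = 2)

#' @rdname grid_visnir
#' @export
grid_nir <- function() seq(908, by = 6.19, length.out = 125)

# Validate a wavelength grid: strictly increasing, uniform step, long enough
# for the Savitzky-Golay window to fit somewhere.
check_grid <- function(wavelengths, min_length = 15) {
  if (!is.numeric(wavelengths) || length(wavelengths) < min_length) {
    abort(sprintf(
      "wavelength grid must be numeric with at least %d points, got %d",
      min_length, length(wavelengths)
    ))
  }
  steps <- diff(wavelengths)
  if (any(steps <= 0)) {
    abort("wavelength grid must be strictly increasing")
  }
  step <- steps[1]
  if (any(abs(steps - step) > 1e-9 * abs(step))) {
    abort("wavelength grid must have a uniform step")
  }
  invisible(step)
}

grid_step <- function(wavelengths) {
  check_grid(wavelengths, min_length = 2)
}
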