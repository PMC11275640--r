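#' Apparent absorbance of repeated white-reference measurements
#'
#' With a perfectly stable instrument, re-measuring the white reference gives
#' an absorbance of exactly zero against itself; whatever deviates from zero
#' is instrument noise. For a series of repeated white/dark acquisitions under
#' one (exposure, integrations) condition, each repeat after the first is
#' referenced to the first:
#' \deqn{A(\lambda, t) = -\log_{10}\frac{W(\lambda,t)-D(\lambda,t)}
#'                                      {W(\lambda,t_0)-D(\lambda,t_0)}}
#' so a series of 20 repeats yields 19 apparent absorbance spectra.
#'
#' @param series A long data frame with columns `wavelength` (nm), `repeat_id`
#'   (integer, 1 = the reference repeat), `white` and `dark` (counts), as
#'   produced by [simulate_plate_series()]. At least 2 repeats; `white - dark`
#'   must be positive everywhere.
#' @return A tibble with columns `repeat_id` (2..n), `wavelength` and
#'   `absorbance` (AU).
#' @export
apparent_absorbance <- function(series) {
  need <- c("wavelength", "repeat_id", "white", "dark")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  reps <- sort(unique(series$repeat_id))
  if (length(reps) < 2) abort("need at least 2 repeats")
  wide <- intensity_matrices(series, reps)
  net <- wide$white - wide$dark
  if (any(net <= 0)) abort("white - dark must be positive everywhere")
  a <- -log10(sweep(net[-1, , drop = FALSE], 2, net[1, ], "/"))
  tibble::tibble(
    repeat_id = rep(reps[-1], each = ncol(a)),
    wavelength = rep(wide$wavelengths, length(reps) - 1),
    absorbance = as.numeric(t(a))
  )
}

# repeats x wavelengths matrices from the long form, wavelength-sorted.
intensity_matrices <- function(series, reps) {
  wl <- sort(unique(series$wavelength))
  check_grid(wl, min_length = 2)
  n_wl <- length(wl)
  ord <- order(series$repeat_id, series$wavelength)
  s <- series[ord, ]
  if (nrow(s) != length(reps) * n_wl) {
    abort("series is ragged: every repeat must cover the full grid once")
  }
  list(
    wavelengths = wl,
    white = matrix(s$white, length(reps), n_wl, byrow = TRUE),
    dark = matrix(s$dark, length(reps), n_wl, byrow = TRUE)
  )
}

#' Standard-deviation spectrum of second-derivative apparent absorbance
#'
#' The apparent absorbance spectra are second-derivative filtered row-wise
#' (same Savitzky-Golay settings as the calibration pipeline), then for every
#' wavelength inside `window_nm` the standard deviation across the repeats is
#' taken, with the N-1 denominator where N is the number of apparent spectra.
#' The window is intersected with the derivative-trimmed grid; on the Vis-NIR
#' preset the canonical 834-872 nm window holds exactly 20 points.
#'
#' @param apparent Output of [apparent_absorbance()].
#' @param window_nm Numeric length-2 vector, inclusive wavelength window (nm).
#' @param window,polyorder Savitzky-Golay settings (see
#'   [sg_second_derivative()]).
#' @return A tibble with columns `wavelength` and `sd` (AU), one row per grid
#'   point in the window; the number of apparent spectra is attached as
#'   attribute `n_spectra`.
#' @export
sd_spectrum <- function(apparent, window_nm, window = 15, polyorder = 2) {
  wl <- sort(unique(apparent$wavelength))
  check_grid(wl, min_length = window)
  reps <- sort(unique(apparent$repeat_id))
  ord <- order(apparent$repeat_id, apparent$wavelength)
  a <- matrix(apparent$absorbance[ord], length(reps), length(wl), byrow = TRUE)
  d2 <- sg_second_derivative(a, window = window, polyorder = polyorder)
  half <- (window - 1) / 2
  wl_trim <- wl[(half + 1):(length(wl) - half)]
  keep <- wl_trim >= window_nm[1] & wl_trim <= window_nm[2]
  if (!any(keep)) {
    abort("window_nm contains no grid points after derivative trimming")
  }
  sds <- apply(d2[, keep, drop = FALSE], 2, sd)   # N-1 denominator
  structure(
    tibble::tibble(wavelength = wl_trim[keep], sd = sds),
    n_spectra = length(reps)
  )
}

#' Scalar noise level from an SD spectrum
#'
#' The noise level (NL) of an acquisition condition is the mean of the
#' per-wavelength standard deviations over the selected window,
#' \eqn{NL = \sum \sigma_\lambda / M}. Units are absorbance (second-derivative
#' scale); well-tuned instruments reach fractions of a micro-absorbance.
#'
#' @param sigma Output of [sd_spectrum()], or a bare numeric vector of
#'   per-wavelength SDs.
#' @return A single non-negative number.
#' @export
noise_level <- function(sigma) {
  if (is.data.frame(sigma)) sigma <- sigma$sd
  if (length(sigma) == 0) abort("empty SD spectrum")
  mean(sigma)
}

#' Noise level over an exposure-by-integration acquisition grid
#'
#' Runs the full noise pipeline — apparent absorbance, second derivative, SD
#' spectrum, scalar NL — for every acquisition condition present in the
#' input, e.g. the 30-condition grid of 6 exposure times crossed with 5
#' integration counts used to characterize an instrument.
#'
#' @param series A long data frame with columns `exposure_ms`, `integrations`,
#'   `wavelength`, `repeat_id`, `white`, `dark`: one repeated white-plate
#'   series per (exposure, integrations) condition, as produced by binding
#'   [simulate_plate_series()] outputs.
#' @inheritParams sd_spectrum
#' @return A tibble sorted by condition with columns `exposure_ms`,
#'   `integrations`, `n_spectra` (apparent spectra per condition), `n_points`
#'   (window grid points) and `nl` (AU).
#' @export
noise_grid <- function(series, window_nm, window = 15, polyorder = 2) {
  need <- c("exposure_ms", "integrations")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  series |>
    dplyr::group_by(.data$exposure_ms, .data$integrations) |>
    dplyr::group_modify(function(grp, key) {
      sig <- tryCatch(
        sd_spectrum(apparent_absorbance(grp), window_nm,
                    window = window, polyorder = polyorder),
        error = function(e) abort(sprintf(
          "condition %g ms x %d integrations: %s",
          key$exposure_ms, key$integrations, conditionMessage(e)
        ))
      )
      tibble::tibble(
        n_spectra = attr(sig, "n_spectra"),
        n_points = nrow(sig),
        nl = noise_level(sig)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$exposure_ms, .data$integrations)
}
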