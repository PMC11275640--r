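#' Absorbance from raw detector counts
#'
#' Converts one raw intensity measurement (sample, white reference, dark
#' current, all in detector counts) into absorbance,
#' \deqn{A(\lambda) = -\log_{10}\frac{S(\lambda)-D(\lambda)}
#'                                   {W(\lambda)-D(\lambda)},}
#' the standard dark-corrected, white-referenced form used in diffuse
#' reflectance spectroscopy.
#'
#' Both net intensities must be strictly positive at every wavelength:
#' a non-positive `sample - dark` or `white - dark` makes the logarithm
#' undefined and raises an error naming the first offending wavelength
#' (silent clipping would bias downstream calibration).
#'
#' @param data Data frame with numeric columns `wavelength` (nm, strictly
#'   increasing, uniform step), `sample`, `white` and `dark` (counts).
#' @return A tibble with columns `wavelength` and `absorbance` (AU).
#' @examples
#' d <- tibble::tibble(
#'   wavelength = seq(500, 978, 2),
#'   sample = 250, white = 1200, dark = 200
#' )
#' compute_absorbance(d) # -log10(50/1000) = 1.30103 everywhere
#' @seealso [average_replicates()], [transmittance_absorbance()]
#' @export
compute_absorbance <- function(data) {
  need <- c("wavelength", "sample", "white", "dark")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  check_grid(data$wavelength, min_length = 2)
  a <- absorbance_values(data$sample, data$white, data$dark, data$wavelength)
  tibble::tibble(wavelength = data$wavelength, absorbance = a)
}

absorbance_values <- function(s, w, d, wavelength) {
  net_w <- w - d
  net_s <- s - d
  bad_w <- which(net_w <= 0)
  if (length(bad_w) > 0) {
    abort(sprintf(
      "white - dark is not positive at wavelength %g nm",
      wavelength[bad_w[1]]
    ))
  }
  bad_s <- which(net_s <= 0)
  if (length(bad_s) > 0) {
    abort(sprintf(
      "sample - dark is not positive at wavelength %g nm",
      wavelength[bad_s[1]]
    ))
  }
  -log10(net_s / net_w)
}

#' Average absorbance over replicate measurement points
#'
#' Fruit spectra are typically acquired at several points around the fruit
#' equator (four points roughly every 60 degrees in the protocol this package
#' models) and reported as one spectrum per fruit. Each replicate is converted
#' to absorbance individually and the absorbances are averaged; averaging is on
#' the absorbance scale, not on raw counts.
#'
#' @param replicates Either a list of data frames, each as accepted by
#'   [compute_absorbance()], or one long data frame with an additional
#'   `replicate` column distinguishing the measurement points. All replicates
#'   must share the same wavelength grid.
#' @return A tibble with columns `wavelength` and `absorbance` (AU).
#' @export
average_replicates <- function(replicates) {
  if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) {
      abort("long-form input needs a `replicate` column")
    }
    replicates <- replicates |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_split(.keep = FALSE)
  }
  if (!is.list(replicates) || length(replicates) == 0) {
    abort("need at least one replicate measurement")
  }
  spectra <- purrr::map(replicates, compute_absorbance)
  wl <- spectra[[1]]$wavelength
  for (s in spectra[-1]) {
    if (length(s$wavelength) != length(wl) ||
        any(abs(s$wavelength - wl) > 1e-9)) {
      abort("replicates do not share a common wavelength grid")
    }
  }
  a <- purrr::map(spectra, "absorbance") |>
    purrr::reduce(`+`) / length(spectra)
  tibble::tibble(wavelength = wl, absorbance = a)
}

#' Transmittance absorbance of a pigment solution
#'
#' Apparent absorbance of a pigment solution measured in transmission against a
#' water reference, computed as
#' \deqn{A(\lambda) = -\log_{10}\frac{I_0(\lambda)}{I_t(\lambda)}}
#' with \eqn{I_0} the reference (water) intensity and \eqn{I_t} the pigment
#' sample intensity.
#'
#' Note the sign convention: with the reference in the numerator, an absorbing
#' sample (\eqn{I_t < I_0}) yields *negative* values. This is the convention of
#' the laboratory protocol this function reproduces; the conventional
#' spectroscopic absorbance is its negation. The convention is deliberately
#' kept as-is rather than silently flipped — band *positions*, which are what
#' the pigment spectra are used for, are unaffected.
#'
#' @param data Data frame with numeric columns `wavelength`, `reference`
#'   (\eqn{I_0}) and `sample` (\eqn{I_t}); intensities must be strictly
#'   positive.
#' @param pigment Optional pigment name attached as a `pigment` column.
#' @return A tibble with columns `wavelength`, `absorbance` and (if given)
#'   `pigment`.
#' @export
transmittance_absorbance <- function(data, pigment = NULL) {
  need <- c("wavelength", "reference", "sample")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(data$reference <= 0 | data$sample <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive intensity at wavelength %g nm", data$wavelength[bad[1]]
    ))
  }
  out <- tibble::tibble(
    wavelength = data$wavelength,
    absorbance = -log10(data$reference / data$sample)
  )
  if (!is.null(pigment)) out$pigment <- pigment
  out
}
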