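#' Tidy the coefficient spectrum of a fitted PLS model
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return A tibble with columns `wavelength` and `coefficient` — the same
#'   table as [coefficient_spectrum()].
#' @export
tidy.plsr_model <- function(x, ...) coefficient_spectrum(x)

#' One-row summary of a fitted PLS model
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_factors`, `n_train`, `n_wavelengths`,
#'   `y_mean`, and (when a PRESS curve is attached) `press` at the selected
#'   factor count.
#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_train = x$trained_on$n %||% NA_integer_,
    n_wavelengths = length(x$coefficients),
    y_mean = x$y_mean,
    press = if (!is.null(x$press)) x$press$press[x$n_factors] else NA_real_
  )
}

#' Tidy a PRESS curve
#'
#' @param x A `press_curve`.
#' @param ... Unused.
#' @return A tibble with `factors`, `press`, the F-ratio against the minimum
#'   PRESS (`f_ratio`) and a logical `selected` column when a selection has
#'   been recorded.
#' @export
tidy.press_curve <- function(x, ...) {
  out <- tibble::tibble(factors = x$factors, press = x$press)
  out$f_ratio <- x$press / min(x$press)
  sel <- attr(x, "selected")
  if (!is.null(sel)) out$selected <- out$factors == sel
  out
}

#' @export
glance.press_curve <- function(x, ...) {
  tibble::tibble(
    h_max = max(x$factors),
    n = attr(x, "n") %||% NA_integer_,
    selected = attr(x, "selected") %||% NA_integer_,
    min_press = min(x$press)
  )
}
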