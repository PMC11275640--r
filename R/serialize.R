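#' Save and load fitted PLS models as JSON
#'
#' Serializes a `plsr_model` (means, per-factor weight/loading vectors,
#' coefficient spectrum, wavelength grid, training descriptor) to a plain
#' JSON file with full double precision, so that a written-then-read model
#' predicts identically to the original. The PRESS curve, when attached, is
#' stored alongside (values only; leave-one-out predictions are not
#' persisted).
#'
#' @param model A `plsr_model`.
#' @param path File path.
#' @return `read_plsr()`: a `plsr_model`. `write_plsr()`: `model`, invisibly.
#' @export
write_plsr <- function(model, path) {
  payload <- list(
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    weights = asplit_cols(model$weights),
    x_loadings = asplit_cols(model$x_loadings),
    y_loadings = model$y_loadings,
    coefficients = model$coefficients,
    n_factors = model$n_factors,
    wavelengths = model$wavelengths,
    trained_on = model$trained_on
  )
  if (!is.null(model$press)) {
    payload$press <- list(
      factors = model$press$factors,
      press = model$press$press,
      n = attr(model$press, "n"),
      selected = attr(model$press, "selected")
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(model)
}

asplit_cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])

#' @rdname write_plsr
#' @export
read_plsr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(cols) {
    if (is.list(cols)) do.call(cbind, cols) else as.matrix(cols)
  }
  model <- structure(
    list(
      x_mean = as.numeric(p$x_mean),
      y_mean = as.numeric(p$y_mean),
      weights = to_mat(p$weights),
      x_loadings = to_mat(p$x_loadings),
      y_loadings = as.numeric(p$y_loadings),
      coefficients = as.numeric(p$coefficients),
      n_factors = as.integer(p$n_factors),
      wavelengths = if (is.null(p$wavelengths)) NULL
                    else as.numeric(p$wavelengths),
      trained_on = p$trained_on
    ),
    class = "plsr_model"
  )
  if (!is.null(p$press)) {
    curve <- structure(
      tibble::tibble(factors = as.integer(p$press$factors),
                     press = as.numeric(p$press$press)),
      n = as.integer(p$press$n),
      selected = as.integer(p$press$selected),
      class = c("press_curve", class(tibble::tibble()))
    )
    model$press <- curve
  }
  model
}
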