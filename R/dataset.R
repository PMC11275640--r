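#' Spectral dataset tibbles
#'
#' Throughout the package a *spectral dataset* is a wide tibble with one row
#' per fruit sample: metadata columns `sample_id` (unique character), `variety`
#' (character) and `ssc` (reference soluble solids content, % Brix), followed
#' by one numeric column per wavelength, named by the wavelength in nm (e.g.
#' `"500"`, `"502"`, ...). The wavelength columns must form a strictly
#' increasing, uniformly spaced grid.
#'
#' `spectra_wavelengths()` returns the grid; `spectra_matrix()` extracts the
#' absorbance block as a numeric matrix (samples x wavelengths);
#' `as_spectra()` assembles a dataset from its parts and validates it.
#'
#' @param data A spectral dataset tibble.
#' @return `spectra_wavelengths()`: numeric vector of wavelengths (nm).
#'   `spectra_matrix()`: numeric matrix, one row per sample.
#' @name spectral-dataset
NULL

meta_cols <- c("sample_id", "variety", "ssc")

#' @rdname spectral-dataset
#' @export
spectra_wavelengths <- function(data) {
  nm <- setdiff(names(data), meta_cols)
  wl <- suppressWarnings(as.numeric(nm))
  if (anyNA(wl)) {
    abort(paste0(
      "non-numeric spectral column name(s): ",
      paste(nm[is.na(wl)], collapse = ", ")
    ))
  }
  wl
}

#' @rdname spectral-dataset
#' @export
spectra_matrix <- function(data) {
  wl <- spectra_wavelengths(data)
  m <- as.matrix(data[, setdiff(names(data), meta_cols)])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  m
}

#' @rdname spectral-dataset
#' @param wavelengths Numeric wavelength grid (nm).
#' @param absorbance Numeric matrix, samples x wavelengths.
#' @param ssc Numeric reference SSC per sample (% Brix), finite and positive.
#' @param variety Character variety label per sample.
#' @param sample_id Character unique id per sample; generated if omitted.
#' @export
as_spectra <- function(absorbance, wavelengths, ssc, variety,
                       sample_id = NULL) {
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (is.null(sample_id)) sample_id <- sprintf("s%03d", seq_len(n))
  if (length(variety) == 1) variety <- rep(variety, n)
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    variety = as.character(variety),
    ssc = as.numeric(ssc)
  )
  spec <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(spec) <- format_wavelength(wavelengths)
  out <- dplyr::bind_cols(out, spec)
  validate_spectra(out)
  out
}

format_wavelength <- function(wl) sprintf("%.10g", wl)

validate_spectra <- function(data, min_grid = 2) {
  for (col in meta_cols) {
    if (!col %in% names(data)) abort(sprintf("missing `%s` column", col))
  }
  wl <- spectra_wavelengths(data)
  check_grid(wl, min_length = min_grid)
  if (ncol(data) - length(meta_cols) != length(wl)) {
    abort("spectral column count mismatch")
  }
  if (anyDuplicated(data$sample_id) > 0) abort("duplicated sample_id")
  if (any(!is.finite(data$ssc)) || any(data$ssc <= 0)) {
    abort("ssc must be finite and positive")
  }
  invisible(data)
}

#' Read and write spectral datasets as CSV
#'
#' The on-disk layout is the same wide form as the in-memory tibble: a UTF-8
#' CSV whose header is `sample_id,variety,ssc,<wavelength1>,<wavelength2>,...`
#' with wavelengths in nm as numeric column names and absorbance values in AU.
#' Values round-trip at full double precision (15 significant digits).
#'
#' @param path File path.
#' @param data A spectral dataset tibble (see [spectra_matrix()]).
#' @return `read_spectra()`: a validated spectral dataset tibble.
#'   `write_spectra()`: `data`, invisibly.
#' @export
read_spectra <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  data$sample_id <- as.character(data$sample_id)
  validate_spectra(data)
  data
}

#' @rdname read_spectra
#' @export
write_spectra <- function(data, path) {
  validate_spectra(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
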