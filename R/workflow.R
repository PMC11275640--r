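#' Run the full calibration experiment over several datasets
#'
#' For every named dataset: second-derivative preprocessing
#' ([derivative_spectra()]), a seeded 7:3 split ([split_spectra()]), PLS
#' training with PRESS/F-ratio factor selection ([plsr_train()]) and
#' three-context validation ([validate_model()]). One summary row per dataset
#' mirrors the conventional calibration table: factor count, calibration,
#' cross-validation and prediction R-squared/RMSE, RPD and the
#' slope/offset/bias of predicted-vs-measured on the test set.
#'
#' A failure in one dataset (for example too few samples) aborts only that
#' row, with a warning carrying the dataset name; other datasets proceed.
#'
#' @param datasets Named list of spectral dataset tibbles (raw absorbance;
#'   preprocessing is applied here).
#' @param window,polyorder Savitzky-Golay settings.
#' @param train_fraction,stratify_by Split settings (see [split_spectra()]).
#' @param h_max,alpha Factor-selection settings (see [plsr_train()]).
#' @param seed Integer seed for the splits; dataset *k* uses `seed + k - 1`.
#' @param output_dir Optional directory; when given, the summary
#'   (`summary.csv`), per-dataset models (`models/<name>.json`), PRESS curves
#'   (`press/<name>.csv`) and validation reports (`reports/<name>.json`) are
#'   written there at full precision.
#' @return A tibble with one row per dataset: the summary columns plus
#'   list-columns `model` (the fitted `plsr_model`, PRESS curve attached) and
#'   `test` (the held-out preprocessed test set, for transfer experiments).
#' @seealso [run_transfer_matrix()]
#' @export
run_experiment <- function(datasets, window = 15, polyorder = 2,
                           train_fraction = 0.7, stratify_by = NULL,
                           h_max = 15, alpha = 0.25, seed = 1,
                           output_dir = NULL) {
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    abort("`datasets` must be a fully named list")
  }
  rows <- purrr::imap(datasets, function(data, name) {
    k <- match(name, names(datasets))
    tryCatch(
      run_one(data, name, window, polyorder, train_fraction, stratify_by,
              h_max, alpha, seed + k - 1L),
      error = function(e) {
        warning(sprintf("dataset `%s` failed: %s", name, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

run_one <- function(data, name, window, polyorder, train_fraction,
                    stratify_by, h_max, alpha, seed) {
  d2 <- derivative_spectra(data, window = window, polyorder = polyorder)
  split <- split_spectra(d2, train_fraction = train_fraction, seed = seed,
                         stratify_by = stratify_by)
  model <- plsr_train(split$train, h_max = h_max, alpha = alpha)
  rep <- validate_model(model, split$train, split$test)
  wide <- rep |>
    dplyr::select("context", "r2", "rmse") |>
    tidyr::pivot_wider(names_from = "context",
                       values_from = c("r2", "rmse"))
  pred <- rep[rep$context == "prediction", ]
  tibble::tibble(
    dataset = name,
    n_train = nrow(split$train),
    n_test = nrow(split$test),
    factors = model$n_factors,
    r2_c = wide$r2_calibration,
    rmsec = wide$rmse_calibration,
    r2_cv = wide$r2_cross_validation,
    rmsecv = wide$rmse_cross_validation,
    r2_p = wide$r2_prediction,
    rmsep = wide$rmse_prediction,
    rpd = pred$rpd,
    slope = pred$slope,
    offset = pred$offset,
    bias = pred$bias,
    model = list(model),
    test = list(split$test)
  )
}

write_experiment <- function(out, output_dir) {
  dir.create(file.path(output_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(output_dir, "press"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "reports"), showWarnings = FALSE)
  summary_cols <- dplyr::select(out, -"model", -"test")
  readr::write_csv(summary_cols, file.path(output_dir, "summary.csv"),
                   progress = FALSE)
  for (i in seq_len(nrow(out))) {
    name <- out$dataset[i]
    model <- out$model[[i]]
    write_plsr(model, file.path(output_dir, "models",
                                paste0(name, ".json")))
    readr::write_csv(tibble::as_tibble(model$press),
                     file.path(output_dir, "press", paste0(name, ".csv")),
                     progress = FALSE)
    jsonlite::write_json(
      as.list(summary_cols[i, ]),
      file.path(output_dir, "reports", paste0(name, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}

#' Cross-evaluate fitted models on foreign test sets
#'
#' Applies every model to every foreign test set through
#' [transfer_validate()] — the calibration-transfer matrix. Pairings whose
#' wavelength grids differ (e.g. a Vis-NIR model against an NIR test set) are
#' skipped, so a mixed-instrument collection yields only the meaningful
#' rows; any other per-pair failure raises a warning naming the pair and the
#' remaining pairs proceed.
#'
#' @param experiment Output tibble of [run_experiment()], or a named list of
#'   `plsr_model` objects.
#' @param tests Named list of preprocessed (second-derivative) spectral
#'   dataset tibbles to predict on. Defaults to the experiment's own held-out
#'   test sets, giving the full matrix including in-domain rows.
#' @return A tibble with one row per (model, test) pair: `model`, `test_set`,
#'   `n`, `factors`, `r2_p`, `rmsep`, `rpd`, `slope`, `offset`, `bias`.
#' @export
run_transfer_matrix <- function(experiment, tests = NULL) {
  if (is.data.frame(experiment)) {
    models <- stats::setNames(experiment$model, experiment$dataset)
    if (is.null(tests)) {
      tests <- stats::setNames(experiment$test, experiment$dataset)
    }
  } else {
    models <- experiment
    if (is.null(tests)) abort("`tests` is required when passing bare models")
  }
  grid <- tidyr::expand_grid(model = names(models), test_set = names(tests))
  rows <- purrr::pmap(grid, function(model, test_set) {
    wl_m <- models[[model]]$wavelengths
    wl_t <- spectra_wavelengths(tests[[test_set]])
    if (!is.null(wl_m) &&
        (length(wl_m) != length(wl_t) || any(abs(wl_m - wl_t) > 1e-6))) {
      return(NULL)   # incompatible instrument grids: not a meaningful pair
    }
    rep <- tryCatch(
      transfer_validate(models[[model]], tests[[test_set]]),
      error = function(e) {
        warning(sprintf("pair %s -> %s failed: %s", model, test_set,
                        conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (is.null(rep)) return(NULL)
    tibble::tibble(
      model = model, test_set = test_set,
      n = rep$n, factors = rep$factors,
      r2_p = rep$r2, rmsep = rep$rmse, rpd = rep$rpd,
      slope = rep$slope, offset = rep$offset, bias = rep$bias
    )
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
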