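small_study <- function(seed = 101) {
  sc <- simulate_transfer_scenario(n_white = 60, n_red = 50, seed = seed)
  sc[c("white", "red")]
}

test_that("the experiment emits one summary row per dataset, deterministically", {
  datasets <- small_study()
  ex <- suppressMessages(run_experiment(datasets, h_max = 8, seed = 5))
  expect_equal(ex$dataset, c("white", "red"))
  expect_equal(ex$n_train + ex$n_test, c(60, 50))
  expect_true(all(ex$factors >= 1))
  expect_true(all(ex$rmsep > 0))

  ex2 <- suppressMessages(run_experiment(datasets, h_max = 8, seed = 5))
  expect_identical(dplyr::select(ex, -model, -test),
                   dplyr::select(ex2, -model, -test))

  # a broken dataset warns and is dropped; the rest proceed
  datasets$tiny <- datasets$white[1:5, ]
  expect_warning(
    ex3 <- suppressMessages(run_experiment(datasets, h_max = 8, seed = 5)),
    "tiny"
  )
  expect_equal(ex3$dataset, c("white", "red"))
})

test_that("summary metrics equal the underlying validation reports", {
  datasets <- small_study(102)
  ex <- suppressMessages(run_experiment(datasets["white"], h_max = 8,
                                        seed = 6))
  m <- ex$model[[1]]
  test <- ex$test[[1]]
  expect_equal(ex$rmsep, rmse(test$ssc, predict(m, test)))
  expect_equal(ex$r2_p, r_squared(test$ssc, predict(m, test)))
  expect_equal(ex$factors, m$n_factors)
  expect_equal(ex$rpd * ex$rmsep, sd(test$ssc), tolerance = 1e-12)
})

test_that("experiment artifacts land on disk and round-trip", {
  out_dir <- withr::local_tempdir()
  datasets <- small_study(103)
  ex <- suppressMessages(
    run_experiment(datasets, h_max = 8, seed = 7, output_dir = out_dir))
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "models", "white.json")))
  expect_true(file.exists(file.path(out_dir, "press", "red.csv")))
  expect_true(file.exists(file.path(out_dir, "reports", "white.json")))

  summary <- readr::read_csv(file.path(out_dir, "summary.csv"),
                             show_col_types = FALSE)
  expect_equal(summary$r2_p, ex$r2_p, tolerance = 1e-12)

  back <- read_plsr(file.path(out_dir, "models", "white.json"))
  expect_equal(predict(back, ex$test[[1]]), predict(ex$model[[1]], ex$test[[1]]))
})

test_that("model JSON serialization is lossless", {
  d <- derivative_spectra(simulate_fruit(40, profile_red(), seed = 104))
  m <- plsr_train(d, h_max = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsr(m, path)
  back <- read_plsr(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$x_mean, m$x_mean)
  expect_equal(back$y_mean, m$y_mean)
  expect_equal(back$wavelengths, m$wavelengths)
  expect_equal(back$n_factors, m$n_factors)
  expect_equal(back$press$press, m$press$press)
  expect_equal(attr(back$press, "selected"), attr(m$press, "selected"))
  expect_equal(predict(back, d), predict(m, d))
})

test_that("the transfer matrix covers compatible pairs and matches in-domain rows", {
  datasets <- small_study(105)
  ex <- suppressMessages(run_experiment(datasets, h_max = 8, seed = 8))
  tm <- run_transfer_matrix(ex)
  # 2 models x 2 test sets, all on one grid -> 4 rows
  expect_equal(nrow(tm), 4)
  own <- tm[tm$model == "white" & tm$test_set == "white", ]
  expect_equal(own$r2_p, ex$r2_p[ex$dataset == "white"])
  expect_equal(own$rmsep, ex$rmsep[ex$dataset == "white"])

  # grid-incompatible pairs are dropped silently
  nir_test <- derivative_spectra(
    simulate_fruit(30, profile_white(), grid = grid_nir(), seed = 106))
  tm2 <- run_transfer_matrix(ex, tests = list(nir = nir_test))
  expect_equal(nrow(tm2), 0)
})

test_that("tidy, glance and autoplot methods cover the result objects", {
  d <- derivative_spectra(simulate_fruit(40, profile_white(), seed = 107))
  m <- plsr_train(d, h_max = 5)
  td <- tidy(m)
  expect_named(td, c("wavelength", "coefficient"))
  expect_equal(nrow(td), length(spectra_wavelengths(d)))
  g <- glance(m)
  expect_equal(g$n_factors, m$n_factors)
  tc <- tidy(m$press)
  expect_true(all(c("factors", "press", "f_ratio", "selected") %in% names(tc)))
  expect_equal(sum(tc$selected), 1)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m$press), "ggplot")
  expect_s3_class(plot_predictions(m, d), "ggplot")
  grid_tbl <- noise_grid(
    simulate_plate_series(10, 8, n_repeats = 6, seed = 108),
    window_nm = c(834, 872))
  expect_s3_class(plot_noise_grid(grid_tbl), "ggplot")
})
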