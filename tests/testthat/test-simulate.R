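test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_fruit(25, profile_red(), seed = 81)
  b <- simulate_fruit(25, profile_red(), seed = 81)
  expect_identical(a, b)
  expect_identical(fruit_truth(a), fruit_truth(b))
  s1 <- simulate_plate_series(60, 16, n_repeats = 5, seed = 82)
  s2 <- simulate_plate_series(60, 16, n_repeats = 5, seed = 82)
  expect_identical(s1, s2)
  # different seeds differ
  expect_false(identical(simulate_fruit(25, profile_red(), seed = 83), a))
})

test_that("SSC distributions match the configured populations", {
  d <- simulate_fruit(180, profile_white(), seed = 84)
  # CLT bound: 3 sigma / sqrt(180) around the configured mean of 10.04
  expect_lt(abs(mean(d$ssc) - 10.04), 3 * 1.29 / sqrt(180))
  expect_lt(abs(sd(d$ssc) - 1.29), 0.35)
  expect_true(all(d$ssc > 0))

  r <- simulate_fruit(150, profile_red(), seed = 85)
  expect_lt(abs(mean(r$ssc) - 8.13), 3 * 1.18 / sqrt(150))
  # configured anthocyanin-SSC correlation of 0.8 shows up in the truth
  tr <- fruit_truth(r)
  expect_gt(cor(tr$anthocyanin, tr$ssc), 0.7)
  expect_lt(cor(tr$anthocyanin, tr$ssc), 0.9)
})

test_that("noise-free spectra are a deterministic function of concentrations", {
  prof <- profile_white()
  prof$anthocyanin_sd <- 0
  prof$chlorophyll_sd <- 0
  truth <- draw_fruit_truth(4, prof, seed = 86)
  truth$ssc <- rep(10, 4)
  truth$sugar <- truth$ssc
  truth$water <- rep(1, 4)
  bp <- baseline_params(offset_sd = 0, slope_sd = 0, curve_sd = 0)
  d <- simulate_fruit(profile = prof, noise_sd = 0, baseline = bp,
                      truth = truth, seed = 87)
  x <- spectra_matrix(d)
  for (i in 2:4) expect_equal(x[i, ], x[1, ], ignore_attr = TRUE)
})

test_that("PLSR on noise-free data recovers SSC and noise degrades it monotonically", {
  d0 <- simulate_fruit(80, profile_white(), noise_sd = 0, seed = 88)
  sp <- split_spectra(derivative_spectra(d0), seed = 89)
  m <- plsr_train(sp$train, h_max = 6)
  rep <- validate_model(m, sp$train, sp$test)
  expect_true(all(rep$r2 > 0.999))

  truth <- draw_fruit_truth(120, profile_white(), seed = 90)
  # same truth and same noise realization (shared seed) scaled by noise_sd:
  # a paired design under which the degradation is monotone
  rmseps <- sapply(c(0.002, 0.01, 0.05, 0.25), function(ns) {
    d <- simulate_fruit(profile = profile_white(), noise_sd = ns,
                        truth = truth, seed = 91)
    sp <- split_spectra(derivative_spectra(d), seed = 99)
    m <- plsr_train(sp$train, h_max = 8)
    rmse(sp$test$ssc, predict(m, sp$test))
  })
  expect_true(all(diff(rmseps) > 0))
})

test_that("the white-plate readout noise follows the configured law", {
  # empirical SD of single readouts (integrations = 1) within 5% at 1e4 draws
  source_level <- 2000; exposure <- 60; read_noise <- 30; dark_level <- 100
  s <- simulate_plate_series(exposure, 1, n_repeats = 42, seed = 92,
                             source_level = source_level,
                             read_noise = read_noise, dark_level = dark_level)
  w <- matrix(s$white, nrow = 42, byrow = TRUE)   # 42 repeats x 240 channels
  expected <- sqrt(read_noise^2 + (dark_level + source_level * exposure))
  emp <- sd(as.numeric(sweep(w, 2, colMeans(w))))  # ~1e4 centered draws
  expect_equal(emp, expected, tolerance = 0.05)

  # averaging integrations shrinks the reported SD by sqrt(integrations)
  s16 <- simulate_plate_series(exposure, 16, n_repeats = 42, seed = 93,
                               source_level = source_level,
                               read_noise = read_noise,
                               dark_level = dark_level)
  w16 <- matrix(s16$white, nrow = 42, byrow = TRUE)
  emp16 <- sd(as.numeric(sweep(w16, 2, colMeans(w16))))
  expect_equal(emp16, expected / 4, tolerance = 0.06)
})

test_that("plate series parameters that break the log domain are rejected", {
  expect_error(
    simulate_plate_series(0.001, 1, source_level = 100, read_noise = 500),
    "non-positive"
  )
  expect_error(simulate_plate_series(10, 8, n_repeats = 1), "n_repeats")
})

test_that("transfer scenario and study assemble consistent datasets", {
  sc <- simulate_transfer_scenario(n_white = 30, n_red = 20, seed = 94)
  expect_named(sc, c("white", "red", "mixed"))
  expect_equal(nrow(sc$mixed), 50)
  expect_equal(sort(unique(sc$mixed$variety)), c("red", "white"))
  expect_false(anyDuplicated(sc$mixed$sample_id) > 0)

  st <- simulate_study(n_white = 30, n_red = 20, seed = 95)
  expect_named(st, c("white_visnir", "red_visnir", "mixed_visnir",
                     "white_nir", "red_nir", "mixed_nir"))
  expect_length(spectra_wavelengths(st$white_visnir), 240)
  expect_length(spectra_wavelengths(st$white_nir), 125)
  # the same fruit truth underlies both instrument ranges
  expect_equal(st$white_visnir$ssc, st$white_nir$ssc)
})
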