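test_that("7:3 splits have the expected sizes and are seed-deterministic", {
  mk <- function(n) matrix_as_spectra(matrix(rnorm(n * 20), n, 20),
                                      y = runif(n, 8, 12))
  d180 <- withr::with_seed(41, mk(180))
  s <- split_spectra(d180, seed = 7)
  expect_equal(nrow(s$train), 126)
  expect_equal(nrow(s$test), 54)
  expect_length(intersect(s$train$sample_id, s$test$sample_id), 0)
  expect_setequal(c(s$train$sample_id, s$test$sample_id), d180$sample_id)

  d150 <- withr::with_seed(42, mk(150))
  s2 <- split_spectra(d150, seed = 7)
  expect_equal(nrow(s2$train), 105)
  expect_equal(nrow(s2$test), 45)

  expect_identical(split_spectra(d180, seed = 7), s)
  s_other <- split_spectra(d180, seed = 8)
  expect_false(identical(s_other$train$sample_id, s$train$sample_id))

  small <- withr::with_seed(43, mk(9))
  expect_error(split_spectra(small, seed = 1), "at least 10")
})

test_that("stratified splits preserve per-variety proportions within 1", {
  x <- withr::with_seed(44, matrix(rnorm(100 * 15), 100, 15))
  d <- as_spectra(x, seq(500, 528, 2), ssc = runif(100, 8, 12),
                  variety = rep(c("white", "red"), c(60, 40)))
  s <- split_spectra(d, seed = 3, stratify_by = "variety")
  tr <- table(s$train$variety)
  expect_equal(unname(tr[["white"]]), 42)
  expect_equal(unname(tr[["red"]]), 28)
})

test_that("a noise-free rank-1 signal is recovered with one factor", {
  # all spectral variation lives in one channel; y is linear in it
  x <- matrix(0.5, 30, 25)
  x[, 7] <- withr::with_seed(45, rnorm(30))
  y <- 10 + 2 * x[, 7]
  d <- matrix_as_spectra(x, y)
  m <- plsr_fit(d, n_factors = 1)
  expect_equal(unname(predict(m, d)), y, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in c(1, 2, 3)) {
    d <- sim_latent(n = 15, p = 6, k = 3, noise = 0.4, seed = seed)
    fit <- nipals_fit(d$x, d$y, h = 6)
    ols <- unname(fitted(lm(d$y ~ d$x)))
    expect_equal(nipals_predict(fit, d$x), ols, tolerance = 1e-8)
  }
})

test_that("NIPALS predictions match an independent PLSR implementation", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:5) {
    d <- sim_latent(n = 18, p = 40, k = 3, noise = 0.1, seed = seed)
    for (h in 1:5) {
      fit <- nipals_fit(d$x, d$y, h)
      ref <- mixOmics::pls(d$x, d$y, ncomp = h, mode = "regression",
                           scale = FALSE)
      ref_pred <- predict(ref, d$x)$predict[, 1, h]
      expect_equal(nipals_predict(fit, d$x), unname(ref_pred),
                   tolerance = 1e-6)
    }
  }
})

test_that("training RMSE is non-increasing in the factor count", {
  d <- sim_latent(n = 25, p = 30, k = 4, noise = 0.2, seed = 9)
  errs <- sapply(1:8, function(h) {
    fit <- nipals_fit(d$x, d$y, h)
    sqrt(mean((d$y - nipals_predict(fit, d$x))^2))
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the model is scale-equivariant in the response", {
  d <- sim_latent(n = 20, p = 15, k = 2, noise = 0.1, seed = 10)
  f1 <- nipals_fit(d$x, d$y, 3)
  f2 <- nipals_fit(d$x, 100 * d$y, 3)
  expect_equal(f2$coefficients, 100 * f1$coefficients, tolerance = 1e-9)
  expect_equal(nipals_predict(f2, d$x), 100 * nipals_predict(f1, d$x),
               tolerance = 1e-9)
})

test_that("prediction respects the centering identity and guards shape", {
  d <- sim_latent(n = 20, p = 12, k = 2, noise = 0.1, seed = 11)
  fit <- nipals_fit(d$x, d$y, 3)
  # predicting the mean spectrum returns the mean response exactly
  expect_equal(nipals_predict(fit, matrix(fit$x_mean, 1)), mean(d$y))
  # duplicating a row duplicates the prediction
  two <- nipals_predict(fit, d$x[c(4, 4), ])
  expect_equal(two[1], two[2])
  m <- plsr_fit(matrix_as_spectra(d$x, d$y - min(d$y) + 1), 3)
  expect_error(predict(m, d$x[, 1:5]), "expects")
  # grid mismatch on tibble input
  other <- matrix_as_spectra(d$x, d$y - min(d$y) + 1,
                             wl = seq(908, by = 6.19, length.out = 12))
  expect_error(predict(m, other), "grid")
})

test_that("degenerate responses are rejected", {
  x <- withr::with_seed(12, matrix(rnorm(200), 20, 10))
  expect_error(nipals_fit(x, rep(5, 20), 2), "zero variance|degenerate")
  expect_error(nipals_fit(x, rnorm(20), 25), "n_factors")
})
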