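# Independent oracles and small generators used across the suite.

# Generic latent-factor regression problem: X = T P' + E, y = T q + e.
sim_latent <- function(n, p, k, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    t_mat <- matrix(rnorm(n * k), n, k)
    p_mat <- matrix(rnorm(p * k), p, k)
    x <- t_mat %*% t(p_mat) + matrix(rnorm(n * p, sd = noise), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    list(x = x, y = drop(t_mat %*% rnorm(k)) + rnorm(n, sd = noise))
  })
}

# Matrix-level access to the internal NIPALS fit (the tests exercise the
# exported tibble interface elsewhere; oracle comparisons want raw matrices).
nipals_fit <- function(x, y, h) {
  asNamespace("specbrix")$nipals_pls(x, y, h)
}

nipals_predict <- function(fit, x) {
  drop(fit$y_mean + sweep(as.matrix(x), 2, fit$x_mean) %*% fit$coefficients)
}

loo_press_matrix <- function(x, y, h_max) {
  asNamespace("specbrix")$loo_press(x, y, h_max)
}

# Brute-force LOO-PRESS oracle: one completely separate refit per (fold, h).
brute_force_press <- function(x, y, h_max) {
  n <- nrow(x)
  sapply(seq_len(h_max), function(h) {
    sum(sapply(seq_len(n), function(i) {
      fit <- nipals_fit(x[-i, , drop = FALSE], y[-i], h)
      (y[i] - nipals_predict(fit, x[i, , drop = FALSE]))^2
    }))
  })
}

# Wrap a plain matrix as a spectral dataset tibble on an arbitrary grid.
matrix_as_spectra <- function(x, y, variety = "test",
                              wl = seq(500, by = 2, length.out = ncol(x))) {
  as_spectra(x, wl, ssc = y, variety = variety)
}

# A tiny raw-intensity measurement table.
intensity_tbl <- function(sample, white, dark, n = 20) {
  tibble::tibble(
    wavelength = seq(500, by = 2, length.out = n),
    sample = rep_len(sample, n), white = rep_len(white, n),
    dark = rep_len(dark, n)
  )
}

# SG second-derivative convolution coefficients, for filter-variance laws.
sg_coefs <- function(window = 15, polyorder = 2) {
  asNamespace("specbrix")$sg_coefficients(window, polyorder)
}
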