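#' Split a spectral dataset into training and test sets
#'
#' Random, disjoint and exhaustive 7:3-style partition of the samples, the
#' standard protocol before calibration. The training set size is
#' `round(train_fraction * n)`. With `stratify_by = "variety"` each variety
#' contributes `round(train_fraction * n_variety)` training samples, so the
#' per-variety proportions are preserved within one sample — useful for the
#' mixed-variety dataset.
#'
#' @param data A spectral dataset tibble (see [spectra_matrix()]), n >= 10.
#' @param train_fraction Fraction of samples assigned to training; default 0.7.
#' @param seed Integer seed making the partition reproducible; the global RNG
#'   state is left untouched.
#' @param stratify_by `NULL` (unstratified, the default) or `"variety"`.
#' @return A list with spectral dataset tibbles `train` and `test`.
#' @export
split_spectra <- function(data, train_fraction = 0.7, seed = NULL,
                          stratify_by = NULL) {
  validate_spectra(data)
  n <- nrow(data)
  if (n < 10) {
    abort("need at least 10 samples to split (leave-one-out factor selection)")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1")
  }
  pick <- function(idx) {
    sample(idx, size = round(train_fraction * length(idx)))
  }
  draw <- function() {
    if (is.null(stratify_by)) {
      pick(seq_len(n))
    } else if (identical(stratify_by, "variety")) {
      unlist(lapply(split(seq_len(n), data$variety), pick), use.names = FALSE)
    } else {
      abort("stratify_by must be NULL or \"variety\"")
    }
  }
  train_idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  train_idx <- sort(train_idx)
  list(train = data[train_idx, ], test = data[-train_idx, ])
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of the reference SSC on the (derivative)
#' spectra, computed by the classical NIPALS algorithm: predictor matrix and
#' response are mean-centered (not variance-scaled — amplitude carries
#' information in derivative spectra), then latent factors are extracted one
#' at a time, each maximizing covariance with the current response residual,
#' with rank-one deflation of the predictors between factors. The per-factor
#' weights, loadings and y-loadings are assembled into a single regression
#' coefficient vector \eqn{b = W (P'W)^{-1} q} mapping a centered spectrum to
#' centered SSC.
#'
#' @param data A spectral dataset tibble; the response is its `ssc` column.
#' @param n_factors Number of latent factors, at most `min(n - 1, p)`.
#' @param max_iter,tol Inner-loop convergence controls of the NIPALS factor
#'   iteration (immediate for a univariate response; kept general).
#' @return An object of class `plsr_model`: a list with elements `x_mean`,
#'   `y_mean`, `weights`, `x_loadings` (both p x h), `y_loadings` (length h),
#'   `coefficients` (length p), `n_factors`, `wavelengths`, and a `trained_on`
#'   descriptor. Supports [predict()], [tidy()], [glance()] and [autoplot()].
#' @seealso [plsr_train()] for fitting with automatic factor selection.
#' @export
plsr_fit <- function(data, n_factors, max_iter = 500, tol = 1e-12) {
  validate_spectra(data)
  x <- spectra_matrix(data)
  fit <- nipals_pls(x, data$ssc, n_factors, max_iter = max_iter, tol = tol)
  fit$wavelengths <- spectra_wavelengths(data)
  fit$trained_on <- dataset_descriptor(data)
  fit
}

dataset_descriptor <- function(data) {
  wl <- spectra_wavelengths(data)
  list(
    varieties = sort(unique(data$variety)),
    range_nm = range(wl),
    n = nrow(data)
  )
}

# Matrix-level NIPALS PLS1. X: n x p, y: length n.
nipals_pls <- function(x, y, n_factors, max_iter = 500, tol = 1e-12) {
  x <- as.matrix(x)
  dimnames(x) <- NULL   # keep model vectors unnamed for clean serialization
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) abort("nrow(x) must equal length(y)")
  if (var(y) == 0) abort("response has zero variance; model is degenerate")
  h_bound <- min(n - 1, p)
  if (n_factors < 1 || n_factors > h_bound) {
    abort(sprintf("n_factors must be in [1, %d]", h_bound))
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  e <- sweep(x, 2, x_mean)     # X residual
  f <- y - y_mean              # y residual
  ww <- matrix(0, p, n_factors)
  pp <- matrix(0, p, n_factors)
  qq <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    u <- f
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(e, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) {
        abort(sprintf("no residual covariance left at factor %d", a))
      }
      w <- w / nw
      t_score <- drop(e %*% w)
      if (sqrt(sum((t_score - t_old)^2)) < tol * sqrt(sum(t_score^2))) break
      if (it == max_iter) {
        abort(sprintf("NIPALS did not converge at factor %d", a))
      }
      t_old <- t_score
      u <- f   # univariate response: scores of y are y itself
    }
    tt <- sum(t_score^2)
    p_load <- drop(crossprod(e, t_score)) / tt
    q_load <- sum(f * t_score) / tt
    e <- e - tcrossprod(t_score, p_load)
    f <- f - t_score * q_load
    ww[, a] <- w
    pp[, a] <- p_load
    qq[a] <- q_load
  }
  structure(
    list(
      x_mean = x_mean, y_mean = y_mean,
      weights = ww, x_loadings = pp, y_loadings = qq,
      coefficients = pls_coefficients(ww, pp, qq, n_factors),
      n_factors = n_factors,
      wavelengths = NULL, trained_on = NULL
    ),
    class = "plsr_model"
  )
}

# b = W (P'W)^{-1} q using the first h factors.
pls_coefficients <- function(ww, pp, qq, h) {
  w_h <- ww[, seq_len(h), drop = FALSE]
  drop(w_h %*% solve(crossprod(pp[, seq_len(h), drop = FALSE], w_h),
                     qq[seq_len(h)]))
}

#' Predict SSC from a fitted PLS model
#'
#' \eqn{\hat y = \bar y + (x - \bar x) b} with the training means and the
#' assembled coefficient vector. When `newdata` is a spectral dataset tibble
#' its wavelength grid must match the model's training grid exactly — a guard
#' against mixing instruments or preprocessing settings in model-transfer
#' experiments.
#'
#' @param object A `plsr_model`.
#' @param newdata A spectral dataset tibble or a numeric matrix with one
#'   spectrum per row (p columns).
#' @param ... Unused.
#' @return Numeric vector of predicted SSC (% Brix).
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    wl <- spectra_wavelengths(newdata)
    if (!is.null(object$wavelengths) &&
        (length(wl) != length(object$wavelengths) ||
         any(abs(wl - object$wavelengths) > 1e-6))) {
      abort("wavelength grid of newdata does not match the model's grid")
    }
    newdata <- spectra_matrix(newdata)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    abort(sprintf(
      "newdata has %d wavelengths but the model expects %d",
      ncol(newdata), length(object$coefficients)
    ))
  }
  drop(object$y_mean +
         sweep(newdata, 2, object$x_mean) %*% object$coefficients)
}

#' @export
print.plsr_model <- function(x, ...) {
  d <- x$trained_on
  cat(sprintf(
    "PLS1 regression model: %d factor(s), %d wavelengths\n",
    x$n_factors, length(x$coefficients)
  ))
  if (!is.null(d)) {
    cat(sprintf(
      "  trained on n = %d [%s], %g-%g nm\n",
      d$n, paste(d$varieties, collapse = "+"), d$range_nm[1], d$range_nm[2]
    ))
  }
  invisible(x)
}

#' Leave-one-out PRESS curve
#'
#' For every candidate factor count `h = 1..h_max`, the prediction error sum
#' of squares \eqn{PRESS(h) = \sum_i (y_i - \hat y_{-i,h})^2}, where
#' \eqn{\hat y_{-i,h}} is the prediction for sample *i* from a model refit on
#' all other samples with *h* factors. Each fold is a genuine NIPALS refit
#' (one deflation sweep to `h_max`, coefficients assembled per `h`); no
#' shortcut update formulas are used.
#'
#' @param data A spectral dataset tibble with at least `h_max + 2` samples.
#' @param h_max Largest candidate factor count.
#' @return A `press_curve`: a tibble with columns `factors` and `press`
#'   (% Brix squared, summed), carrying the per-sample LOO predictions
#'   (attribute `predictions`, an n x h_max matrix), the response (`y`) and
#'   the training sample count (`n`).
#' @export
press_curve <- function(data, h_max) {
  validate_spectra(data)
  x <- spectra_matrix(data)
  loo_press(x, data$ssc, h_max)
}

loo_press <- function(x, y, h_max) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < h_max + 2) {
    abort(sprintf("h_max = %d needs at least %d samples, got %d",
                  h_max, h_max + 2, n))
  }
  preds <- matrix(NA_real_, n, h_max)
  for (i in seq_len(n)) {
    fit <- nipals_pls(x[-i, , drop = FALSE], y[-i], h_max)
    xc <- x[i, ] - fit$x_mean
    for (h in seq_len(h_max)) {
      b_h <- pls_coefficients(fit$weights, fit$x_loadings, fit$y_loadings, h)
      preds[i, h] <- fit$y_mean + sum(xc * b_h)
    }
  }
  press <- colSums((y - preds)^2)
  structure(
    tibble::tibble(factors = seq_len(h_max), press = press),
    predictions = preds, y = y, n = n,
    class = c("press_curve", class(tibble::tibble()))
  )
}

#' Select the PLS factor count from a PRESS curve
#'
#' Adopting the factor count that minimizes PRESS tends to overfit; instead
#' the smallest factor count whose PRESS is *not significantly larger* than
#' the minimum is chosen (the Haaland-Thomas rule). For each `h` up to the
#' argmin `h*`, the ratio `F(h) = PRESS(h)/PRESS(h*)` is compared with the
#' upper critical value of an F distribution with `(n, n)` degrees of freedom
#' at probability `alpha`; the smallest `h` whose ratio does not exceed it is
#' selected. `alpha = 0.25` is the probability level recommended in the
#' originating methodology. Ties in the argmin go to the smallest `h`; a zero
#' minimum PRESS short-circuits to `h*` itself.
#'
#' @param curve A `press_curve` from [press_curve()].
#' @param alpha Significance probability of the F test, in (0, 1).
#' @return Integer: the selected factor count.
#' @export
select_factors <- function(curve, alpha = 0.25) {
  press <- curve$press
  n <- attr(curve, "n")
  if (length(press) == 0) abort("empty PRESS curve")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  h_star <- which.min(press)           # ties: smallest h
  if (press[h_star] <= 0) return(h_star)
  f_crit <- qf(1 - alpha, n, n)
  ratios <- press[seq_len(h_star)] / press[h_star]
  which(ratios <= f_crit)[1]
}

#' Fit a PLS model with automatic factor selection
#'
#' The full training procedure: leave-one-out [press_curve()] up to `h_max`
#' factors, [select_factors()] at probability `alpha`, then a final
#' [plsr_fit()] on the whole training set at the selected factor count. The
#' PRESS curve (with its `selected` attribute) is attached to the returned
#' model as `$press`.
#'
#' @inheritParams press_curve
#' @inheritParams select_factors
#' @param data A spectral dataset tibble (typically second-derivative
#'   spectra from [derivative_spectra()]).
#' @return A `plsr_model` (see [plsr_fit()]) with the `press_curve` in
#'   `$press` and `attr(model$press, "selected")` set.
#' @export
plsr_train <- function(data, h_max = 15, alpha = 0.25) {
  curve <- press_curve(data, h_max)
  h <- select_factors(curve, alpha)
  attr(curve, "selected") <- h
  model <- plsr_fit(data, n_factors = h)
  model$press <- curve
  model
}
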