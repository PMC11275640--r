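#' Variety profiles for the synthetic strawberry generator
#'
#' Statistical profiles of the two fruit populations the simulator emulates.
#' SSC is drawn from a normal distribution matching the reported field data:
#' mean 10.04, SD 1.29 % Brix for the white-skinned variety and mean 8.13,
#' SD 1.18 % Brix for the red variety. White fruit carry little anthocyanin
#' and relatively more chlorophyll; red fruit carry abundant anthocyanin
#' whose concentration is positively correlated with SSC
#' (`pigment_ssc_correlation`, default 0.8) — pigment accumulates with
#' ripeness, which is exactly the confound that makes visible-range
#' calibration transfer across skin colors interesting. The secondary
#' anthocyanin band sits near 550 nm in white and 560 nm in red fruit.
#'
#' @param pigment_ssc_correlation Correlation between anthocyanin
#'   concentration and SSC, in \[-1, 1\].
#' @return A named list of profile parameters understood by
#'   [simulate_fruit()].
#' @export
profile_white <- function(pigment_ssc_correlation = 0) {
  list(
    name = "white",
    ssc_mean = 10.04, ssc_sd = 1.29,
    anthocyanin_mean = 0.10, anthocyanin_sd = 0.04,
    chlorophyll_mean = 0.60, chlorophyll_sd = 0.15,
    pigment_ssc_correlation = pigment_ssc_correlation,
    anthocyanin_shift_nm = 550
  )
}

#' @rdname profile_white
#' @export
profile_red <- function(pigment_ssc_correlation = 0.8) {
  list(
    name = "red",
    ssc_mean = 8.13, ssc_sd = 1.18,
    anthocyanin_mean = 1.00, anthocyanin_sd = 0.30,
    chlorophyll_mean = 0.30, chlorophyll_sd = 0.10,
    pigment_ssc_correlation = pigment_ssc_correlation,
    anthocyanin_shift_nm = 560
  )
}

#' Absorption band table for strawberry constituents
#'
#' Gaussian band definitions (center, SD-width, amplitude per unit
#' concentration) for the four constituents of the additive Beer-Lambert
#' mixture: anthocyanin (505 nm plus a variety-shifted band near 550/560 nm),
#' chlorophyll (673 nm), sugar (838, 970, 1168, 1187, 1459 nm; concentration
#' in % Brix) and water (952, 976, 1075, 1416 nm). Pigment bands are narrow
#' (12-14 nm); NIR water/sugar overtone bands broad (28-40 nm). Bands outside
#' a given instrument grid simply contribute nothing there — in particular no
#' pigment band reaches the 908-1676 nm NIR grid.
#'
#' @param anthocyanin_shift_nm Center of the variety-dependent secondary
#'   anthocyanin band.
#' @return A tibble with columns `constituent`, `center_nm`, `width_nm`,
#'   `amplitude`.
#' @export
strawberry_bands <- function(anthocyanin_shift_nm = 555) {
  tibble::tribble(
    ~constituent, ~center_nm, ~width_nm, ~amplitude,
    "anthocyanin", 505, 12, 0.30,
    "anthocyanin", anthocyanin_shift_nm, 14, 0.20,
    "chlorophyll", 673, 12, 0.35,
    "sugar", 838, 28, 0.010,
    "sugar", 970, 30, 0.015,
    "sugar", 1168, 35, 0.012,
    "sugar", 1187, 35, 0.012,
    "sugar", 1459, 40, 0.015,
    "water", 952, 30, 0.35,
    "water", 976, 30, 0.45,
    "water", 1075, 35, 0.30,
    "water", 1416, 40, 0.80
  )
}

#' Draw per-fruit constituent concentrations
#'
#' The generative truth behind a synthetic dataset: SSC from the profile's
#' normal distribution (resampled while non-positive, preserving the normal
#' shape at these means), sugar concentration equal to SSC (unit affine map),
#' anthocyanin correlated with the SSC z-score at the profile's
#' `pigment_ssc_correlation`, chlorophyll and water independent.
#'
#' @param n Number of fruit.
#' @param profile A variety profile, e.g. [profile_white()].
#' @param seed Optional integer seed (global RNG untouched).
#' @return A tibble with columns `sample_id`, `variety`, `ssc`, `sugar`,
#'   `anthocyanin`, `chlorophyll`, `water`.
#' @export
draw_fruit_truth <- function(n, profile, seed = NULL) {
  run <- function() {
    z <- rnorm(n)
    ssc <- profile$ssc_mean + profile$ssc_sd * z
    while (any(bad <- ssc <= 0)) {
      z[bad] <- rnorm(sum(bad))
      ssc[bad] <- profile$ssc_mean + profile$ssc_sd * z[bad]
    }
    rho <- profile$pigment_ssc_correlation
    anth <- profile$anthocyanin_mean + profile$anthocyanin_sd *
      (rho * z + sqrt(1 - rho^2) * rnorm(n))
    tibble::tibble(
      sample_id = sprintf("%s_%03d", profile$name, seq_len(n)),
      variety = profile$name,
      ssc = ssc,
      sugar = ssc,
      anthocyanin = pmax(anth, 0),
      chlorophyll = pmax(
        profile$chlorophyll_mean + profile$chlorophyll_sd * rnorm(n), 0),
      water = 1 + 0.01 * rnorm(n)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a fruit spectral dataset
#'
#' Generates diffuse-reflectance-style absorbance spectra with the structure
#' the calibration pipeline assumes: an additive Beer-Lambert mixture of
#' Gaussian constituent bands on a smooth per-sample scattering baseline
#' (offset + gentle tilt + curvature), plus i.i.d. Gaussian instrument noise
#' added independently to each of `replicate_count` simulated measurement
#' points before they are averaged — mirroring the four-points-per-fruit
#' acquisition protocol.
#'
#' The per-sample constituent concentrations used are attached as attribute
#' `"truth"` and can be retrieved with [fruit_truth()].
#'
#' @param n Number of fruit, or `NULL` when `truth` is supplied.
#' @param profile A variety profile ([profile_white()], [profile_red()]).
#' @param grid Wavelength grid (nm), e.g. [grid_visnir()] or [grid_nir()].
#' @param bands Band table; defaults to [strawberry_bands()] with the
#'   profile's anthocyanin shift.
#' @param noise_sd SD of the additive absorbance noise per replicate point
#'   (AU). Default 0.01.
#' @param replicate_count Measurement points averaged per fruit. Default 4.
#' @param baseline Length-6 list of baseline parameters
#'   (`offset_mean/sd`, `slope_mean/sd`, `curve_mean/sd`).
#' @param truth Optionally a truth table from [draw_fruit_truth()], so the
#'   same fruit can be "measured" on several instrument grids.
#' @param seed Optional integer seed (global RNG untouched).
#' @return A spectral dataset tibble (see [spectra_matrix()]) with the truth
#'   table attached.
#' @export
simulate_fruit <- function(n = NULL, profile = profile_white(),
                           grid = grid_visnir(), bands = NULL,
                           noise_sd = 0.01, replicate_count = 4,
                           baseline = baseline_params(), truth = NULL,
                           seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (replicate_count < 1) abort("replicate_count must be >= 1")
  if (is.null(bands)) {
    bands <- strawberry_bands(profile$anthocyanin_shift_nm)
  }
  run <- function() {
    tr <- truth %||% draw_fruit_truth(n, profile)
    m <- nrow(tr)
    clean <- constituent_spectra(tr, bands, grid) +
      baseline_spectra(m, grid, baseline)
    noisy <- clean
    if (noise_sd > 0) {
      acc <- matrix(0, m, length(grid))
      for (r in seq_len(replicate_count)) {
        acc <- acc + matrix(rnorm(m * length(grid), sd = noise_sd),
                            m, length(grid))
      }
      noisy <- clean + acc / replicate_count
    }
    out <- as_spectra(noisy, grid, ssc = tr$ssc, variety = tr$variety,
                      sample_id = tr$sample_id)
    attr(out, "truth") <- tr
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @rdname simulate_fruit
#' @param data A dataset produced by [simulate_fruit()].
#' @export
fruit_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) abort("no truth table attached to this dataset")
  tr
}

#' @rdname simulate_fruit
#' @param offset_mean,offset_sd,slope_mean,slope_sd,curve_mean,curve_sd
#'   Per-sample scattering baseline: `offset + slope*u + curve*u^2` with `u`
#'   the wavelength position rescaled to \[0, 1\].
#' @export
baseline_params <- function(offset_mean = 0.8, offset_sd = 0.08,
                            slope_mean = 0.2, slope_sd = 0.05,
                            curve_mean = 0, curve_sd = 0.03) {
  list(offset_mean = offset_mean, offset_sd = offset_sd,
       slope_mean = slope_mean, slope_sd = slope_sd,
       curve_mean = curve_mean, curve_sd = curve_sd)
}

constituent_spectra <- function(truth, bands, grid) {
  m <- nrow(truth)
  out <- matrix(0, m, length(grid))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    conc <- truth[[b$constituent]]
    if (is.null(conc)) abort(sprintf("unknown constituent `%s`", b$constituent))
    shape <- exp(-(grid - b$center_nm)^2 / (2 * b$width_nm^2))
    out <- out + b$amplitude * tcrossprod(conc, shape)
  }
  out
}

baseline_spectra <- function(m, grid, bp) {
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  b0 <- rnorm(m, bp$offset_mean, bp$offset_sd)
  b1 <- rnorm(m, bp$slope_mean, bp$slope_sd)
  b2 <- rnorm(m, bp$curve_mean, bp$curve_sd)
  tcrossprod(b0, rep(1, length(u))) + tcrossprod(b1, u) + tcrossprod(b2, u^2)
}

#' Simulate a repeated white-plate intensity series
#'
#' Emulates the repeated white-reference acquisitions used to characterize
#' instrument noise. Per repeat and wavelength the detector accumulates
#' `source_level * exposure_ms` source counts on top of a `dark_level`
#' pedestal; a single readout has noise SD
#' `sqrt(read_noise^2 + shot_factor * mean_counts)`, and the reported
#' intensity is the average of `integrations` independent readouts. Dark
#' frames are generated the same way with the source off. Parameter sets for
#' which the net intensity `white - dark` would be non-positive with
#' probability above 1e-6 are rejected.
#'
#' @param exposure_ms Exposure time per readout (ms).
#' @param integrations Number of readouts averaged.
#' @param n_repeats Repeats of the full acquisition (>= 2; the first is the
#'   reference for [apparent_absorbance()]). Default 20.
#' @param grid Wavelength grid (nm).
#' @param source_level Source counts per ms at the detector.
#' @param read_noise Per-readout noise SD in counts (exposure-independent).
#' @param shot_factor Variance contributed per accumulated count
#'   (1 = ideal shot noise; 0 disables it).
#' @param dark_level Dark pedestal in counts.
#' @param seed Optional integer seed (global RNG untouched).
#' @return A long tibble with columns `exposure_ms`, `integrations`,
#'   `repeat_id`, `wavelength`, `white`, `dark`, ready for
#'   [apparent_absorbance()] and [noise_grid()].
#' @export
simulate_plate_series <- function(exposure_ms, integrations, n_repeats = 20,
                                  grid = grid_visnir(), source_level = 2000,
                                  read_noise = 30, shot_factor = 1,
                                  dark_level = 100, seed = NULL) {
  if (n_repeats < 2) abort("n_repeats must be >= 2")
  if (exposure_ms <= 0 || integrations < 1) {
    abort("exposure_ms must be positive and integrations >= 1")
  }
  net_mean <- source_level * exposure_ms
  white_mean <- dark_level + net_mean
  sd_white <- sqrt(read_noise^2 + shot_factor * white_mean)
  sd_dark <- sqrt(read_noise^2 + shot_factor * dark_level)
  sd_net <- sqrt(sd_white^2 + sd_dark^2) / sqrt(integrations)
  if (net_mean - stats::qnorm(1 - 1e-6) * sd_net <= 0) {
    abort("white - dark would be non-positive with probability > 1e-6; raise source_level, exposure_ms or integrations")
  }
  p <- length(grid)
  run <- function() {
    draw <- function(mean_counts, sd1) {
      # average of `integrations` independent readouts
      matrix(rnorm(n_repeats * p, mean_counts, sd1 / sqrt(integrations)),
             n_repeats, p)
    }
    white <- draw(white_mean, sd_white)
    dark <- draw(dark_level, sd_dark)
    tibble::tibble(
      exposure_ms = exposure_ms,
      integrations = as.integer(integrations),
      repeat_id = rep(seq_len(n_repeats), each = p),
      wavelength = rep(grid, n_repeats),
      white = as.numeric(t(white)),
      dark = as.numeric(t(dark))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the cross-variety transfer scenario
#'
#' Generates the three datasets of the calibration-transfer experiment on one
#' instrument grid: a white population (no pigment-SSC confound), a red
#' population (anthocyanin correlated with SSC) and their concatenation. The
#' two populations use seeds derived deterministically from `seed`.
#'
#' @param n_white,n_red Sample counts; defaults 180 and 150, the study scale.
#' @inheritParams simulate_fruit
#' @param seed Integer seed.
#' @return A list of three spectral dataset tibbles: `white`, `red`, `mixed`.
#' @export
simulate_transfer_scenario <- function(n_white = 180, n_red = 150,
                                       grid = grid_visnir(), noise_sd = 0.01,
                                       seed = 1) {
  white <- simulate_fruit(n_white, profile_white(), grid = grid,
                          noise_sd = noise_sd, seed = seed)
  red <- simulate_fruit(n_red, profile_red(), grid = grid,
                        noise_sd = noise_sd, seed = seed + 1L)
  list(white = white, red = red,
       mixed = dplyr::bind_rows(white, red))
}

#' Simulate the full six-dataset study
#'
#' The complete synthetic stand-in for the study design: white, red and mixed
#' populations, each "measured" on both the Vis-NIR (500-978 nm / 2 nm) and
#' NIR (908-1676 nm / 6.19 nm) grids. The same per-fruit constituent truth is
#' reused across the two grids, as if the same fruit were presented to both
#' instruments.
#'
#' @inheritParams simulate_transfer_scenario
#' @return A named list of six spectral dataset tibbles:
#'   `white_visnir`, `red_visnir`, `mixed_visnir`, `white_nir`, `red_nir`,
#'   `mixed_nir`.
#' @export
simulate_study <- function(n_white = 180, n_red = 150, noise_sd = 0.01,
                           seed = 1) {
  truth_w <- draw_fruit_truth(n_white, profile_white(), seed = seed)
  truth_r <- draw_fruit_truth(n_red, profile_red(), seed = seed + 1L)
  make <- function(truth, profile, grid, sub_seed) {
    simulate_fruit(profile = profile, grid = grid, noise_sd = noise_sd,
                   truth = truth, seed = sub_seed)
  }
  w_vis <- make(truth_w, profile_white(), grid_visnir(), seed + 2L)
  r_vis <- make(truth_r, profile_red(), grid_visnir(), seed + 3L)
  w_nir <- make(truth_w, profile_white(), grid_nir(), seed + 4L)
  r_nir <- make(truth_r, profile_red(), grid_nir(), seed + 5L)
  list(
    white_visnir = w_vis, red_visnir = r_vis,
    mixed_visnir = dplyr::bind_rows(w_vis, r_vis),
    white_nir = w_nir, red_nir = r_nir,
    mixed_nir = dplyr::bind_rows(w_nir, r_nir)
  )
}
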