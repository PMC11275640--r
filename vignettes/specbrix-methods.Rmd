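---
title: "Estimating soluble solids from Vis-NIR and NIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating soluble solids from Vis-NIR and NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(specbrix)
library(dplyr)
```

## The problem

Soluble solids content (SSC, % Brix) is the main sweetness and ripeness
indicator for fruit, conventionally measured by squeezing juice onto a
refractometer — destructive and slow. Diffuse reflectance spectroscopy in the
visible–near-infrared (Vis-NIR, here 500–978 nm at 2 nm) and near-infrared
(NIR, 908–1676 nm at 6.19 nm) ranges offers a non-destructive alternative:
sugar and water O–H/C–H overtone and combination bands modulate the spectrum
in proportion to composition, and a multivariate calibration maps spectra to
SSC.

The scientifically interesting wrinkle is skin pigmentation. White-skinned
strawberry varieties carry little anthocyanin, so ripeness cannot be judged
by color, which makes spectroscopic SSC estimation especially valuable for
them — but it also means a calibration built on red fruit sees large pigment
absorption (anthocyanin near 505 and 550–560 nm, chlorophyll near 673 nm)
that white fruit lack. Whether a model *transfers* across skin colors then
depends on whether its wavelength range contains pigment information at all.
This package implements the full pipeline needed to study that question, and
a synthetic data generator that reproduces its statistical structure so every
stage is testable without the original fruit.

## Pipeline overview

1. **Absorbance**: raw detector counts are converted per wavelength as
   `A = -log10((S - D) / (W - D))` with sample `S`, white reference `W` and
   dark current `D` (`compute_absorbance()`); the four measurement points per
   fruit are averaged on the absorbance scale (`average_replicates()`).
2. **Preprocessing**: a Savitzky–Golay second derivative
   (`derivative_spectra()`, window 15, polynomial order 2) removes baseline
   offset and tilt exactly and sharpens overlapping bands.
3. **Calibration**: NIPALS partial least squares regression of SSC on the
   derivative spectra (`plsr_train()`), with the factor count chosen from a
   leave-one-out PRESS curve by an F-ratio rule.
4. **Validation**: R², RMSE for calibration / cross-validation / prediction,
   RPD, and the slope/offset/bias of predicted-versus-measured
   (`validate_model()`); cross-population evaluation via
   `transfer_validate()` and `run_transfer_matrix()`.
5. **Instrument noise**: a scalar noise level (NL) per acquisition condition
   from repeated white-reference measurements (`noise_grid()`).

## The regression model

PLS1 is fit by classical NIPALS: `X` (n × p derivative spectra) and `y`
(SSC) are mean-centered — not variance-scaled, since amplitude carries
information in derivative spectra — and factors are extracted one at a time.
Each factor's weight vector is proportional to `X'y` on the current
residuals, scores are `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`, and
`X`, `y` are deflated by the rank-one factor contribution. The per-factor
quantities assemble into a single coefficient vector `b = W(P'W)^{-1}q`, so
prediction is `ŷ = ȳ + (x - x̄)b`. The inner NIPALS iteration is kept
general (tolerance 1e-12, cap 500 iterations) although it converges in one
pass for a univariate response.

**Factor selection.** Choosing the factor count `h` that minimizes the
leave-one-out PRESS, `PRESS(h) = Σᵢ(yᵢ - ŷ₋ᵢ,ₕ)²`, tends to overfit.
Instead the smallest `h` whose PRESS is not significantly larger than the
minimum is selected: each ratio `PRESS(h)/PRESS(h*)` up to the argmin `h*`
is compared with the upper critical value of an F distribution with (n, n)
degrees of freedom at probability α = 0.25 — the probability level
recommended in the methodology this rule comes from. Both `h_max`
(default 15) and α are exposed. Ties in the argmin go to the smallest `h`;
a zero minimum PRESS short-circuits to `h*`. Every leave-one-out fold is a
genuine refit (one NIPALS sweep to `h_max` per fold, coefficients assembled
per `h`); no shortcut update formulas are used, preferring transparency at
these problem sizes (n ≤ ~230, p ≤ 226).

**Validation metrics.** `rmse()` is `sqrt(mean((ŷ - y)²))`. `r_squared()`
is `1 - Σ(y - ŷ)²/Σ(y - ȳ)²`, which can be negative for models worse than
the mean predictor — transfer experiments produce exactly such values.
`rpd()` divides the test-set SD (n−1 convention, with a population-SD
option) by the RMSE; the conventional reading of its bands is available as
`rpd_class()`. Slope and offset regress *predicted on measured*, so an
over-responsive model shows slope > 1 with a compensating negative offset.
Bias is `mean(ŷ - y)` and always satisfies |bias| ≤ RMSE.

## The noise-level statistic

Re-measuring a white reference against itself should give exactly zero
absorbance; the deviation is instrument noise. For each acquisition
condition (exposure time × number of integrations) a series of repeats is
referenced to its first measurement,
`A(λ,t) = -log10((W(λ,t) - D(λ,t))/(W(λ,t₀) - D(λ,t₀)))`, so 20 repeats
yield 19 apparent absorbance spectra. These are second-derivative filtered
with the same settings as the calibration pipeline, the per-wavelength SD
across repeats (N−1 denominator, N = 19 apparent spectra) is taken inside a
fixed window — 834–872 nm on the Vis-NIR grid, exactly 20 points — and NL is
the mean of those SDs. NL is invariant to a common gain on the net
intensities, zero iff the apparent derivative spectra are identical in the
window, and for injected i.i.d. absorbance noise of SD `s` equals
`s × sqrt(Σc²ₖ)`, the root-sum-square of the filter coefficients — all three
properties are tested.

## The synthetic generator

`simulate_fruit()` produces absorbance spectra as an additive Beer–Lambert
mixture of Gaussian constituent bands on a smooth per-sample scattering
baseline, plus i.i.d. absorbance noise added per simulated measurement point
(4 points, matching the acquisition protocol) before averaging. The
configured populations follow the reported field statistics: SSC ~
Normal(10.04, 1.29) for white and Normal(8.13, 1.18) for red fruit
(resampled while non-positive). Sugar concentration equals SSC (unit affine
map); anthocyanin is correlated with the SSC z-score at 0.8 in the red
profile (pigment accumulates with ripeness — the transfer confound) and
uncorrelated in the white profile; chlorophyll and water are independent.
Band centers follow the assignments observable in second-derivative fruit
spectra: anthocyanin 505 and 550 (white) / 560 (red) nm, chlorophyll 673 nm,
sugar 838, 970, 1168, 1187, 1459 nm, water 952, 976, 1075, 1416 nm. Widths
(12–14 nm visible, 28–40 nm NIR) are chosen so second-derivative peaks
resolve at window 15; band amplitudes and the noise SD (0.01 AU per
replicate point) were chosen once so that study-scale calibrations land in
the reported performance regime (prediction R² ≈ 0.85–0.95, RMSEP ≈ 0.4 %
Brix, RPD ≈ 3, single-digit factor counts).

What the generator deliberately does **not** emulate: multiplicative
scattering effects and path-length variation (no radiative transfer), band
shape asymmetries, temperature sensitivity of the water bands, detector
nonlinearity, and wavelength-correlated noise. Passing tests therefore show
that the *pipeline* recovers the structure this model encodes, not that any
particular instrument will achieve these numbers on real fruit.

`simulate_plate_series()` emulates the white-plate noise acquisitions: mean
counts proportional to exposure, per-readout noise
`sqrt(read_noise² + shot_factor × counts)`, and averaging over the
configured number of integrations. Read-noise-dominated settings reproduce
the `1/sqrt(integrations)` law; raising exposure at fixed integrations
lowers NL, the behavior of a weak-source NIR instrument.

## A worked transfer experiment

```{r transfer, eval = FALSE}
study <- simulate_study(n_white = 180, n_red = 150, seed = 1)
experiment <- run_experiment(study, h_max = 15, alpha = 0.25, seed = 101)
experiment |> select(dataset, factors, r2_p, rmsep, rpd)

transfer <- run_transfer_matrix(experiment)
transfer |> filter(model != test_set)
```

On the Vis-NIR grid the red-fruit model collapses on white fruit (its
anthocyanin proxy is absent there, and the large pigment mean shift turns
into bias), while on the NIR grid — which contains no pigment bands —
transfer in both directions is essentially free. This contrast between
ranges is the robust, repeatable signature; which Vis-NIR direction degrades
more varies with the split, since large pigment mean shifts can also
amplify small spurious coefficients of the white model.

## Numerical choices and edge cases

* Second-derivative values are in index units (AU per grid-point²); on a
  uniform grid this differs from per-nm scaling only by `step²`, which the
  linear calibration absorbs. A `per_nm` option is provided.
* Filter edges are trimmed — 7 points per side at window 15 — rather than
  padded; padding would fabricate data that leaks into calibration.
  The trimmed Vis-NIR grid is 514–964 nm (226 points).
* The filter's frequency response attenuates fast oscillations: relative to
  the analytic `-ω²` law the deviation is ~4% at a 60-sample period and
  below 2% from ~90 samples; tests assert the exact LTI response.
* Non-positive net intensities (`S - D` or `W - D`) are errors naming the
  offending wavelength, never clipped.
* Pigment solution absorbance keeps its source convention
  `-log10(I₀/Iₜ)` — negative for absorbing samples; see
  `?transmittance_absorbance`.
* The split is a uniform random permutation under a user seed (unstratified
  by default; per-variety stratification available for mixed datasets).
* Seeds are handled with `withr`, leaving the caller's RNG state untouched;
  derived seeds are small fixed offsets.

## Problem sizes used in the test suite

The suite exercises the pipeline at the study scale (n = 180/150, 240 and
125 channels, `h_max` 15) for the calibration and transfer properties — 10
seeds each — and at small n (6–20) for the oracle equivalences: NIPALS
against an independent PLSR implementation and against OLS at full rank, and
leave-one-out PRESS against a brute-force refit-per-fold loop. Noise-law
checks use 200–400 repeats so Monte-Carlo error stays well inside the
asserted bands. The full suite runs in about a minute.

## Known limitations

* PLS1 only (single response); no variable selection, interval PLS, or
  orthogonal signal correction.
* No interpolation between instrument grids: models apply only to data on
  their exact training grid, by design.
* The F-ratio selection rule's degrees of freedom (n, n) follow the cited
  methodology; other df conventions exist and would shift selection by at
  most a factor or two in borderline curves.
* Reported accuracies on synthetic data characterize the generator +
  pipeline combination, not any physical instrument.
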