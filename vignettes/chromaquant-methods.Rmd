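---
title: "Models and methods behind chromaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaquant)
```

`chromaquant` automates targeted quantitation of 2D HPLC-FD chromatograms.
This vignette documents the statistical model behind each stage, the
parameters that matter, the numerical choices made where the method left
room, and what the synthetic-data validation does and does not establish.

## Signal model

A chromatogram is a strictly increasing time vector $t$ (minutes) with an
intensity vector $I$ (arbitrary fluorescence units). We model the signal as

$$ I(t) = \sum_k A_k\, g_k(t) + b(t) + \varepsilon(t), $$

a sum of peak shapes (Gaussian, or exponentially modified Gaussian for
tailing peaks) on a low-order polynomial baseline $b$ with additive white
detector noise $\varepsilon \sim N(0, \sigma_n^2)$. The sampling interval
$t_m$ is taken as the median of successive time differences, which is
robust to occasional dropped scans.

## Background and noise

The background/noise estimator slides a window of $w$ consecutive points
over a region and picks the window with the smallest mean; the background
is that mean and the noise its standard deviation. The estimator is exact
(it equals an exhaustive scan — asserted against a brute-force oracle in
the tests), deterministic (ties go to the earliest window), and slightly
biased low in the mean for pure noise (it selects a minimum of sample
means); the bias is below $3\sigma_n/\sqrt{w}$ at the default $w = 100$.

The baseline fitter partitions the region into consecutive blocks of
`baseline_points` (default 100) points, takes each block's
minimum-intensity point as a support point, and least-squares fits a
polynomial of degree `baseline_order` (default 1) through the supports.
Block minima rather than noise-window means were chosen because minima
reliably dodge narrow peaks riding on the drift; the strategy recovers a
known linear drift under 5 % in the presence of peaks. Both strategies are
defensible; this one is fixed and documented rather than inferred.

## Peak detection (FOD-GPD)

Detection iterates four steps on the residual signal inside the region of
interest:

1. **Spline.** A univariate smoothing spline is fitted to the residual.
   The smoothing level follows the classic heuristic of targeting a
   residual sum of squares of $n \sigma_n^2$; because R's
   `stats::smooth.spline` parameterises smoothing by `spar` rather than an
   RSS target, the target is met by a monotone bisection over `spar`.
   When no noise scale is available, generalized cross-validation picks
   the penalty instead. `spline_smoothing = 0` forces an interpolating
   spline (useful on noiseless fixtures, too wiggly under noise).
2. **Brackets.** Local maxima of the spline's first derivative are paired
   with the next local minimum; each pair $[t_{\max}, t_{\min}]$ brackets
   one candidate apex (about $\mu \pm \sigma$ for a Gaussian). Extrema
   whose derivative magnitude is below $10^{-6}$ of the largest are
   discarded — they are floating-point wiggles on flat stretches, not
   peaks.
3. **Fit.** The bracket containing the globally highest residual point is
   fitted with $a(t) = A e^{-(t-\mu)^2/2\sigma^2}$ above the constant
   background, by bounded L-BFGS-B least squares (start: $A$ = bracket max
   − background, $\mu$ = bracket argmax, $\sigma$ = bracket width / 4;
   bounds $A > 0$, $t_m < \sigma <$ bracket width). A failed fit masks the
   apex point and the loop continues.
4. **Subtract.** The fitted Gaussian is subtracted over the whole region;
   negative residuals are kept unclipped so that
   $\sum_k \text{area}_k + \int \text{residual} = \int \text{input}$
   holds to within the fit tolerance (measured < 2 %).

The loop stops when the highest background-subtracted residual falls below
`cutoff_fraction` (default 1 %) of the initial background-subtracted
maximum, or at `max_iterations` (default 50, with a warning). The spline is
refitted over the whole region each iteration; refitting only unsubtracted
segments would save time but complicates the bracket bookkeeping for no
measured accuracy gain at desk scale. Detected peaks export as a peak list
named `peak1..peakN` with half-window FWHM/2; the displayed bracket is
narrower (≈ 2σ), and the FWHM-based window is the stored one.

A deliberate consequence of the Gaussian model: a strongly tailing
(exponentially modified) peak is resolved as *several* Gaussians. That is
the documented behavior, not a defect — the tail genuinely carries area —
and it is why automatically detected peak lists should be curated before
quantitation.

## Retention-time calibration

Calibrant apexes are located as the highest data point within
$t_r \pm \Delta t_r$ (the data-point apex, not the spline apex — the
spline apex is reserved for the $r_t$ QC criterion; on grids at the
default 0.01 min spacing the difference is below $t_m$). Calibrants under
the S/N gate (default 9) are rejected. With at least `min_calibrants`
(default 4, minimum 3) survivors, a 2nd-degree polynomial $f_p$ maps
observed to expected retention times and the whole axis is transformed as
$t_{new} = f_p(t_{original})$. With exactly 3 calibrants the fit
interpolates; with more it is least squares. If $f_p$ is non-monotone over
the data range the new axis would fold back on itself, so calibration
fails loudly rather than producing a corrupt chromatogram; failed samples
are excluded from batch aggregation and logged, never silently passed
through uncalibrated.

## Quantitation

$$ A_p = \sum_{i \in \text{window}} t_m (I_i - \text{background}), $$

over the closed window $[t_r - \Delta t_r,\; t_r + \Delta t_r]$ (a
boundary point belongs to the window; a relative $\sqrt{\epsilon}$
tolerance keeps grid points on the boundary from dropping out through
floating-point noise). The background is estimated *locally* per analyte:
the lowest-average run of points within ± `background_window` (default
1.0 min) around the analyte window, using a run length equal to the number
of points spanning the analyte window itself (minimum 10). Local
backgrounds track drift better than one global estimate and match the
definition of the S/N criterion; background subtraction can be disabled
via `subtract_background`. Negative point contributions are retained so
that linearity holds. Relative areas normalise over the successfully
quantified analytes; windows that fall outside the data are flagged and
excluded from the denominator.

## Quality-control criteria

* $r_t = |t_r(\text{obs}) - t_r(\text{exp})|$, with the observed apex the
  continuous argmax of an interpolating spline through the window points
  (dense evaluation at 10× sampling resolution, then local refinement —
  deterministic, sub-$t_m$ resolution).
* $S/N = (\max I - \text{background})/\text{noise}$.
* $GPQ$ = analytic area of a Gaussian fitted to the background-subtracted
  window points, divided by the background-subtracted integrated area.
  The ratio direction (Gaussian area in the numerator) follows the
  operational definition of the method; the inverse convention appears in
  some descriptions, and since curation thresholds are symmetric around 1
  (|GPQ − 1|), the choice does not affect flagging. GPQ ≈ 1 for clean
  Gaussians, and deviates by more than 0.1 for a τ = 3σ tail or for a
  half-overlapping neighbor intruding into the analyte window.

## Synthetic data: the stated world

The generator produces Gaussian/EMG peaks on a polynomial baseline with
white noise; all randomness derives from an explicit seed (replicate seeds
derive affinely from the master seed, identically on every platform, and
the global RNG stream is saved and restored). The EMG is parameterised to
preserve the Gaussian area $A\sigma\sqrt{2\pi}$ as τ grows, so
ground-truth areas stay valid for tailing peaks. Warp coefficients record
where each peak would sit on a reference time axis, which is exactly what
calibration must recover.

Validation scenarios and their fixed parameters:

* **Detection recovery** (100 seeded simulations): 3–10 peaks,
  σ = 0.05 min, amplitudes uniform 20–100 against noise σ = 1 (S/N
  20–100), spacing uniform 5–10 σ, $t_m$ = 0.01 min. These were chosen
  once as a realistic mostly-resolved profile honoring the floors
  "S/N ≥ 10, spacing ≥ 4σ". Asserted: 100 % recall, every center within
  $t_m$, and mean |area error| < 5 % within every simulation. Individual
  low-amplitude peaks show stochastic area errors up to ≈ 8 %: a
  three-parameter fit on a ≈ 2σ bracket at S/N ≈ 20 is variance-limited,
  so the 5 % bound holds at the per-simulation mean, not per peak.
* **Calibration recovery**: warp $-0.05 + 1.01 t + 0.002 t^2$ over 11–25
  min, calibrant centers snapped to the sampling grid; recovery is then
  exact to numerical precision and post-calibration residuals sit at
  machine epsilon — the test tolerances ($t_m$, 1 %) are ceilings, not
  targets.
* **QC fixtures**: the tailing and overlap GPQ fixtures are evaluated
  through the package's own default analyte window (± 0.15 min, centered
  on the expected $t_r$) — the window a targeted assay would actually
  use. Over a much wider window a free Gaussian fit broadens to absorb a
  tail or a symmetric double peak and GPQ drifts back towards 1; the
  criterion is a *windowed* shape check, not a global goodness-of-fit.
* **Replicate CV**: 9 replicates of a 7-peak profile with 1 % lognormal
  amplitude CV and 0.002 min center jitter; measured CVs are compared to
  1 % within the chi-distribution tolerance $3/\sqrt{2(n-1)}$.

What a green suite does **not** establish: performance on real detector
artifacts (spikes, saturation, gradient dwell ripple), non-white or
heteroscedastic noise, severely fronting peaks, or vendor export layouts
other than the two documented text dialects — the true vendor field
layouts vary by instrument configuration, and the parsers implement a
declared, fixture-backed approximation.

## Degenerate inputs and tie-breaks

Flat signals yield zero brackets (not an error); equal-height apexes and
lowest-mean ties resolve to the earliest time; an empty analyte window is
an error for single-peak operations and a flagged row in batch
quantitation; zero estimated noise is an error directing the user to a
larger noise window; all floating-point output uses 6 significant digits
with `.` decimal so batch reruns are byte-identical.

## Known limitations

Quantitation assumes the analyte list is curated; overlapping analytes
share integrated area between overlapping windows rather than being
deconvolved (mixture-model deconvolution is out of scope). Calibration
needs identifiable calibrant peaks — there is no feature-based alignment.
The CLI reads whole chromatograms into memory; typical HPLC-FD exports
(10³–10⁵ points) are far below any practical limit.
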