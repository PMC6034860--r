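# chromaquant

Batch processing and quantitation of HPLC-FD chromatograms in R.

High-performance liquid chromatography with fluorescence detection (HPLC-FD)
is a workhorse for quantifying labelled glycans, glycopeptides and other
biomolecules. Modern columns push sample throughput far beyond what
point-and-click vendor software comfortably processes, so studies with
dozens to hundreds of injections need an automated, scriptable pipeline.
`chromaquant` provides that pipeline for 2D (retention time vs. intensity)
chromatograms exported as plain text: automated peak detection,
calibrant-based retention-time calibration, integration-based quantitation,
per-analyte quality control and replicate batch statistics — plus a seeded
synthetic-chromatogram generator so every stage can be validated against
known ground truth.

## The methods in brief

* **Background & noise** — slide a window of *w* consecutive points over the
  signal; the window with the lowest mean defines the background (its mean)
  and noise (its standard deviation).
* **Peak detection (first-derivative spline + Gaussian fit-and-subtract)** —
  fit a smoothing spline to the region of interest, locate the local maxima
  and minima of its first derivative f′(x) (each max→min pair brackets one
  candidate apex), fit a Gaussian
  a(t) = A·exp(−(t−μ)²/2σ²) above the background to the bracket holding
  the highest remaining data point, subtract it, and repeat until the
  highest residual falls below a user cutoff (default 1 % of the initial
  maximum). Detected peaks become a peak list (name, t_r = μ,
  half-window = FWHM/2, FWHM = 2√(2 ln 2)·σ).
* **Retention-time calibration** — per calibrant, the observed t_r is the
  apex data point within t_r ± Δt_r; calibrants below an S/N threshold are
  dropped; a 2nd-degree polynomial f_p is least-squares fitted through the
  retained (t_r(obs), t_r(exp)) pairs and applied as
  t_r(new) = f_p(t_r(original)).
* **Quantitation** — A_p = Σᵢ t_m·(Iᵢ − background) over the closed analyte
  window, with t_m the sampling interval; relative areas normalise over the
  analyte list.
* **Quality control** — r_t = |t_r(obs) − t_r(exp)| with the observed apex
  from an interpolating spline; S/N = (window max − background)/noise;
  GPQ = (area of a fitted Gaussian)/(background-subtracted integrated
  area), ≈ 1 for clean Gaussian peaks and ≠ 1 for tailing, fronting or
  overlapping ones.
* **Batch statistics** — per-analyte mean relative area, SD and
  CV = 100·sd/mean across replicate injections, and the derived Fab
  glycosylation metric
  100·(G2S2_total/G2S2_fab)/(G1F_total/G1F_fc).

## Worked example

Nine replicate injections of a 7-peak glycopeptide-like profile with 1 %
injected amplitude CV are simulated, peaks are auto-detected on the first
replicate, and the whole folder is calibrated and quantified:

```r
library(chromaquant)

spec <- example_profile_spec(seed = 11)
dir.create(raw <- tempfile("raw"))
reps <- simulate_replicates(spec, 9, area_cv = 0.01, shift_sd = 0.002)
for (i in seq_along(reps))
  write_chromatogram_dialect(reps[[i]], file.path(raw, sprintf("rep%d.txt", i)),
                             "chromeleon_txt")

ch <- read_chromatogram(file.path(raw, "rep1.txt"))
peaks <- detect_peaks(ch, detection_settings(c(11, 25), cutoff_fraction = 0.01))
print(peaks[, c("center", "sigma", "amplitude", "area")], digits = 4)
#>   center   sigma amplitude   area
#> 1   12.5 0.05005    247.57  31.06
#> 2   14.0 0.05000    905.31 113.47
#> 3   15.8 0.05995    393.68  59.15
#> 4   17.2 0.04989    154.21  19.29
#> 5   18.1 0.05007    599.79  75.28
#> 6   20.5 0.05990     80.46  12.08
#> 7   23.0 0.07124     40.49   7.23

calibrants <- suggest_calibrants(peaks, k = 4)
analytes   <- peaks_to_definitions(peaks)
batch <- run_batch(raw, analytes, calibrants = calibrants,
                   config = processing_config(), out_dir = tempfile("out"))
print(batch)
#> <batch_summary> 9 sample(s), 0 failed
#>    name mean_area_rel  sd_area_rel   cv_pct n
#> 1 peak1    0.09682095 0.0022987371 2.374215 9
#> 2 peak2    0.34962198 0.0040672689 1.163333 9
#> 3 peak3    0.19105841 0.0041396303 2.166683 9
#> 4 peak4    0.05831029 0.0007133755 1.223413 9
#> 5 peak5    0.24172608 0.0044722059 1.850113 9
#> 6 peak6    0.03969040 0.0011032939 2.779750 9
#> 7 peak7    0.02277189 0.0003966733 1.741943 9
```

All seven true peaks are recovered with centers on the simulated values and
areas within a few percent of A·σ·√(2π). The replicate CVs sit at 1–3 %:
the 1 % injected amplitude CV plus integration noise through the narrow
auto-detected FWHM/2 windows. Widening the windows (e.g. the
`quant_window = 0.15` min default with a user-curated peak list) tightens
them towards the injected 1 %.

## Command line

```sh
Rscript inst/cli/chromaquant.R detect    --input run1.txt --start 11 --end 25 --cutoff 0.01 --out peaks.tsv
Rscript inst/cli/chromaquant.R calibrate --input raw/ --calibrants cal.tsv --min-sn 9 --min-calibrants 4 --out cal/
Rscript inst/cli/chromaquant.R batch     --input cal/ --analytes peaks.tsv --out results/
Rscript inst/cli/chromaquant.R simulate  --out synth/ --n 9 --seed 1 --format chromeleon
```

Example configuration files for the two bundled processing profiles live in
`inst/extdata/*.cfg`.

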