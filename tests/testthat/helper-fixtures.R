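# Shared fixtures and independent oracles.

# a noise_estimate with known values, bypassing estimation
fixed_noise <- function(background = 0, noise = 1) {
  structure(list(background = background, noise = noise,
                 window_start = 0, window_points = 100L),
            class = "noise_estimate")
}

flat_chromatogram <- function(value = 5, n = 200, tm = 0.01) {
  chromatogram(seq(0, by = tm, length.out = n), rep(value, n))
}

# brute-force O(n*w) oracle for the lowest-average window
brute_force_noise <- function(time, intensity, w) {
  n <- length(intensity)
  best_mean <- Inf; best_i <- NA_integer_
  for (i in 1:(n - w + 1)) {
    m <- mean(intensity[i:(i + w - 1)])
    if (m < best_mean) { best_mean <- m; best_i <- i }
  }
  run <- intensity[best_i:(best_i + w - 1)]
  list(background = mean(run), noise = sd(run), window_start = time[best_i])
}

# one seeded multi-peak detection scenario with ground truth
# (3-10 peaks, sigma 0.05 min, S/N 20-100, spacing 5-10 sigma, noise sd 1)
detection_case <- function(seed) {
  set.seed(seed)
  k <- sample(3:10, 1)
  sigma <- 0.05
  centers <- 1 + cumsum(runif(k, 5 * sigma, 10 * sigma))
  amps <- runif(k, 20, 100)
  spec <- sim_spec(peak_spec(centers, sigma, amps), 0, max(centers) + 1,
                   tm = 0.01, noise_sd = 1, seed = seed * 3 + 1)
  simulate_chromatogram(spec)
}

run_detection_case <- function(seed) {
  ch <- detection_case(seed)
  gt <- attr(ch, "ground_truth")
  ne <- estimate_background_noise(ch, window_points = 50)
  st <- detection_settings(range(ch$time), 0.05)
  pk <- detect_peaks(ch, st, ne)
  err <- vapply(seq_len(nrow(gt)), function(i) {
    d <- abs(pk$center - gt$center[i])
    j <- which.min(d)
    c(d[j], abs(pk$area[j] - gt$area[i]) / gt$area[i])
  }, numeric(2))
  res <- attr(pk, "residual")
  tm <- 0.01
  input_int <- sum(tm * ch$intensity)
  list(chrom = ch, gt = gt, peaks = pk,
       center_err = err[1, ], area_err = err[2, ],
       conservation = abs(sum(pk$area) + sum(tm * res$intensity) -
                            input_int) / max(abs(input_int), 1))
}
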