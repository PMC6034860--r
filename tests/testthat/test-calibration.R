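test_that("find_observed_tr picks the apex data point with tie-breaks", {
  spec <- sim_spec(peak_spec(10, 0.05, 100), 9, 11, tm = 0.01, seed = 1)
  ch <- simulate_chromatogram(spec)
  expect_equal(find_observed_tr(ch, list(tr = 10, window = 0.2)), 10,
               tolerance = 0.011)

  # monotone rising: right edge wins
  ch <- chromatogram(seq(0, 1, by = 0.1), seq(0, 1, by = 0.1))
  expect_equal(find_observed_tr(ch, list(tr = 0.5, window = 0.2)), 0.7)

  # tie: earliest point wins
  ch <- chromatogram(seq(0, 1, by = 0.1), rep(3, 11))
  expect_equal(find_observed_tr(ch, list(tr = 0.5, window = 0.2)), 0.3)

  expect_error(find_observed_tr(ch, list(tr = 5, window = 0.2)),
               "no data points")
})

test_that("identity calibration leaves the time axis unchanged", {
  spec <- sim_spec(peak_spec(c(12, 15, 18, 22), 0.05, 100), 11, 25,
                   tm = 0.01, noise_sd = 0.5, seed = 7)
  ch <- simulate_chromatogram(spec)
  cal <- peak_list(paste0("c", 1:4), c(12, 15, 18, 22), rep(0.3, 4))
  r <- calibrate(ch, cal, min_sn = 9, min_calibrants = 4)
  expect_equal(r$chromatogram$time, ch$time, tolerance = 1e-9)
  expect_equal(r$result$coefficients, c(0, 1, 0), tolerance = 1e-7)
  expect_equal(nrow(r$result$used), 4L)
})

test_that("a degree-2 warp is recovered and residuals vanish", {
  warp <- c(-0.05, 1.01, 0.002)
  centers <- c(12, 15, 18, 22) # snapped to the 0.01 min grid
  spec <- sim_spec(peak_spec(centers, 0.05, 100), 11, 25, tm = 0.01,
                   noise_sd = 0.5, warp = warp, seed = 7)
  ch <- simulate_chromatogram(spec)
  expected <- attr(ch, "ground_truth")$center_ref
  cal <- peak_list(paste0("c", 1:4), expected, rep(1.5, 4))
  r <- calibrate(ch, cal, min_sn = 9, min_calibrants = 4)
  expect_equal(r$result$coefficients, warp, tolerance = 0.01)
  tm <- sampling_interval(ch)
  for (i in 1:4) {
    obs <- find_observed_tr(r$chromatogram,
                            list(tr = expected[i], window = 0.3))
    expect_lt(abs(obs - expected[i]), tm)
  }
})

test_that("S/N gating rejects weak calibrants and can fail calibration", {
  spec <- sim_spec(peak_spec(c(12, 15, 18, 22), 0.05, c(100, 100, 100, 2)),
                   11, 25, tm = 0.01, noise_sd = 0.5, seed = 12)
  ch <- simulate_chromatogram(spec)
  cal <- peak_list(paste0("c", 1:4), c(12, 15, 18, 22), rep(0.3, 4))
  expect_error(calibrate(ch, cal, min_sn = 9, min_calibrants = 4),
               "3 of 4 calibrants retained")
  # with min_calibrants = 3 the same input calibrates
  r <- calibrate(ch, cal, min_sn = 9, min_calibrants = 3)
  expect_equal(nrow(r$result$used), 3L)
  expect_equal(r$result$rejected$name, "c4")
  expect_match(r$result$rejected$reason, "S/N")
})

test_that("exactly 3 retained calibrants interpolate exactly", {
  spec <- sim_spec(peak_spec(c(12, 16, 21), 0.05, 100), 11, 25, tm = 0.01,
                   seed = 3)
  ch <- simulate_chromatogram(spec)
  expected <- c(12.1, 16.05, 20.9)
  cal <- peak_list(paste0("c", 1:3), expected, rep(0.5, 3))
  r <- calibrate(ch, cal, min_sn = 9, min_calibrants = 3,
                 noise = fixed_noise())
  f <- r$result$coefficients
  obs <- r$result$used$observed
  expect_equal(f[1] + f[2] * obs + f[3] * obs^2, expected, tolerance = 1e-9)
})

test_that("calibration is idempotent and rejects non-monotone fits", {
  spec <- sim_spec(peak_spec(c(12, 15, 18, 22), 0.05, 100), 11, 25,
                   tm = 0.01, noise_sd = 0.3, warp = c(0.1, 1.005, 0.0005),
                   seed = 19)
  ch <- simulate_chromatogram(spec)
  expected <- attr(ch, "ground_truth")$center_ref
  cal <- peak_list(paste0("c", 1:4), expected, rep(0.8, 4))
  r1 <- calibrate(ch, cal, min_sn = 9, min_calibrants = 4)
  r2 <- calibrate(r1$chromatogram, cal, min_sn = 9, min_calibrants = 4)
  tm <- sampling_interval(ch)
  expect_lt(max(abs(r2$chromatogram$time - r1$chromatogram$time)), tm)

  # observed apexes (12, 15, 18, 22) paired with expected (12, 18, 21, 22)
  # give a quadratic that bends back over the data range
  spec <- sim_spec(peak_spec(c(12, 15, 18, 22), 0.05, c(100, 90, 80, 70)),
                   11, 25, tm = 0.01, seed = 3)
  ch <- simulate_chromatogram(spec)
  bad <- peak_list(paste0("c", 1:4), c(12, 18, 21, 22),
                   c(0.3, 3.2, 3.2, 0.3))
  expect_error(calibrate(ch, bad, min_sn = 0, min_calibrants = 4,
                         noise = fixed_noise()),
               "non-monotone")
  expect_error(calibrate(ch, bad, min_sn = 0, min_calibrants = 2),
               ">= 3")
})
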