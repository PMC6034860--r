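test_that("derivative brackets isolate clean apexes and flat signals give none", {
  spec <- sim_spec(peak_spec(5, 0.05, 100), 4, 6, tm = 0.01, seed = 1)
  ch <- simulate_chromatogram(spec)
  st <- detection_settings(c(4, 6), 0.05, spline_smoothing = 0)
  br <- derivative_brackets(ch, st)
  expect_equal(nrow(br), 1L)
  expect_true(br$lo[1] < 5 && 5 < br$hi[1])

  expect_equal(nrow(derivative_brackets(flat_chromatogram(1, 100),
                                        detection_settings(c(0, 1), 0.05))),
               0L)

  spec2 <- sim_spec(peak_spec(c(4.5, 5.5), 0.05, c(80, 60)), 4, 6,
                    tm = 0.01, seed = 1)
  br2 <- derivative_brackets(simulate_chromatogram(spec2), st)
  expect_equal(nrow(br2), 2L)
  expect_true(br2$lo[1] < 4.5 && 4.5 < br2$hi[1])
  expect_true(br2$lo[2] < 5.5 && 5.5 < br2$hi[2])

  expect_error(derivative_brackets(flat_chromatogram(1, 5),
                                   detection_settings(c(0, 1), 0.05)),
               "10 data points")
})

test_that("three disjoint Gaussians are recovered with centers and areas", {
  spec <- sim_spec(peak_spec(c(3, 5, 7), 0.05, c(100, 50, 10)), 0, 10,
                   tm = 0.01, noise_sd = 0.5, seed = 3)
  ch <- simulate_chromatogram(spec)
  ne <- estimate_background_noise(ch, window_points = 100)
  pk <- detect_peaks(ch, detection_settings(c(0, 10), 0.05), ne)
  expect_equal(nrow(pk), 3L)
  expect_equal(pk$center, c(3, 5, 7), tolerance = 0.01 / 3)
  truth <- c(100, 50, 10) * 0.05 * sqrt(2 * pi)
  expect_equal(pk$area, truth, tolerance = 0.05)
  expect_equal(pk$fwhm, 2 * sqrt(2 * log(2)) * pk$sigma)
})

test_that("a 50% cutoff keeps exactly the single dominant peak", {
  spec <- sim_spec(peak_spec(5, 0.05, 100), 4, 6, tm = 0.01, noise_sd = 0.5,
                   seed = 8)
  ch <- simulate_chromatogram(spec)
  pk <- detect_peaks(ch, detection_settings(c(4, 6), 0.5),
                     estimate_background_noise(ch, window_points = 50))
  expect_equal(nrow(pk), 1L)
})

test_that("a tailing EMG peak is resolved as multiple Gaussians", {
  spec <- sim_spec(peak_spec(5, 0.05, 100, tau = 0.15), 4, 7, tm = 0.01,
                   noise_sd = 0.5, seed = 4)
  ch <- simulate_chromatogram(spec)
  pk <- detect_peaks(ch, detection_settings(c(4, 7), 0.05),
                     estimate_background_noise(ch, window_points = 100))
  expect_gte(nrow(pk), 2L)
})

test_that("area is conserved between fitted peaks and residual", {
  for (seed in c(2, 13, 27)) {
    out <- run_detection_case(seed)
    expect_lt(out$conservation, 0.02)
  }
})

test_that("lowering the cutoff never loses peaks and output is deterministic", {
  ch <- detection_case(21)
  ne <- estimate_background_noise(ch, window_points = 50)
  counts <- vapply(c(0.5, 0.2, 0.05, 0.02), function(cf) {
    nrow(detect_peaks(ch, detection_settings(range(ch$time), cf), ne))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  st <- detection_settings(range(ch$time), 0.05)
  p1 <- detect_peaks(ch, st, ne)
  p2 <- detect_peaks(ch, st, ne)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("max_iterations truncates with a warning", {
  ch <- detection_case(31)
  ne <- estimate_background_noise(ch, window_points = 50)
  st <- detection_settings(range(ch$time), 0.01, max_iterations = 1L)
  expect_warning(pk <- detect_peaks(ch, st, ne), "max_iterations")
  expect_equal(nrow(pk), 1L)
  expect_true(attr(pk, "truncated"))
})

test_that("peaks_to_definitions names peaks in order with FWHM half-windows", {
  spec <- sim_spec(peak_spec(10, 0.05, 100), 9, 11, tm = 0.01, seed = 1)
  ch <- simulate_chromatogram(spec)
  pk <- detect_peaks(ch, detection_settings(c(9, 11), 0.5), fixed_noise())
  defs <- peaks_to_definitions(pk)
  expect_equal(defs$name, "peak1")
  expect_equal(defs$tr, 10, tolerance = 1e-3)
  expect_equal(defs$window, 2.3548 * 0.05 / 2, tolerance = 0.01)

  out <- run_detection_case(17)
  defs <- peaks_to_definitions(out$peaks)
  expect_equal(defs$name, sprintf("peak%d", seq_len(nrow(defs))))
  expect_true(all(diff(defs$tr) > 0))

  empty <- structure(data.frame(), class = c("detected_peaks", "data.frame"))
  expect_error(peaks_to_definitions(empty), "no detected peaks")
})

test_that("suggest_calibrants spaces picks across the span with fallback", {
  mk_peaks <- function(center, amplitude, sigma = 0.05) {
    structure(data.frame(center = center, sigma = sigma,
                         amplitude = amplitude,
                         fwhm = 2.3548 * sigma,
                         area = amplitude * sigma * sqrt(2 * pi),
                         bracket_lo = center - sigma,
                         bracket_hi = center + sigma,
                         iteration = seq_along(center)),
              class = c("detected_peaks", "data.frame"))
  }
  # 8 evenly spaced equal peaks: one pick per quartile
  pk <- mk_peaks(seq(1, 8), rep(50, 8))
  cal <- suggest_calibrants(pk, 4)
  expect_equal(nrow(cal), 4L)
  expect_true(all(diff(cal$tr) > 1)) # spread across quartiles

  # all mass in the first quartile: falls back to the 4 tallest overall
  pk <- mk_peaks(c(1, 1.1, 1.2, 1.3, 1.4, 8), c(10, 20, 30, 40, 50, 5))
  cal <- suggest_calibrants(pk, 4)
  expect_equal(nrow(cal), 4L)

  pk <- mk_peaks(c(2, 5), c(10, 90))
  cal1 <- suggest_calibrants(pk, 1)
  expect_equal(cal1$tr, 5)
  expect_warning(suggest_calibrants(pk, 4), "only 2 peaks")
})
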