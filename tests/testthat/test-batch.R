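write_replicate_dir <- function(dir, n = 5, seed = 1, corrupt = 0L) {
  spec <- example_profile_spec(seed = seed)
  reps <- simulate_replicates(spec, n, area_cv = 0.01, shift_sd = 0.002)
  for (i in seq_along(reps)) {
    write_chromatogram(reps[[i]], file.path(dir, sprintf("rep%02d.tsv", i)))
  }
  if (corrupt > 0L) {
    writeLines(c("1.0\t2.0", "0.5\tjunk"),
               file.path(dir, "corrupt.tsv"))
  }
  spec
}

test_that("run_batch aggregates replicates and matches recomputation", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  spec <- write_replicate_dir(dir, n = 5, seed = 31)
  analytes <- peak_list(paste0("GP", 1:7), spec$peaks$center, rep(0.15, 7))
  bs <- run_batch(dir, analytes, config = processing_config(),
                  out_dir = out)
  expect_equal(bs$n_samples, 5L)
  expect_equal(nrow(bs$failed), 0L)
  expect_equal(bs$summary$n, rep(5L, 7))

  # independent recomputation from the per-sample TSVs on disk
  files <- list.files(out, pattern = "_results\\.tsv$", full.names = TRUE)
  expect_length(files, 5L)
  tabs <- lapply(files, read.delim)
  for (nm in bs$summary$name) {
    vals <- vapply(tabs, function(tb) tb$area_rel[tb$name == nm], numeric(1))
    expect_equal(bs$summary$mean_area_rel[bs$summary$name == nm], mean(vals),
                 tolerance = 1e-4) # TSVs carry 6 significant digits
    expect_equal(bs$summary$cv_pct[bs$summary$name == nm],
                 100 * sd(vals) / mean(vals), tolerance = 0.02)
  }
})

test_that("batch outputs are byte-identical across reruns", {
  dir <- withr::local_tempdir()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  spec <- write_replicate_dir(dir, n = 3, seed = 8)
  analytes <- peak_list(paste0("GP", 1:7), spec$peaks$center, rep(0.15, 7))
  run_batch(dir, analytes, out_dir = out1)
  run_batch(dir, analytes, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("single replicates report n=1 without a CV", {
  dir <- withr::local_tempdir()
  spec <- write_replicate_dir(dir, n = 1, seed = 2)
  analytes <- peak_list(paste0("GP", 1:7), spec$peaks$center, rep(0.15, 7))
  bs <- run_batch(dir, analytes)
  expect_equal(bs$summary$n, rep(1L, 7))
  expect_true(all(is.na(bs$summary$cv_pct)))
})

test_that("corrupt files are reported but never abort the batch", {
  dir <- withr::local_tempdir()
  spec <- write_replicate_dir(dir, n = 5, seed = 13, corrupt = 1L)
  analytes <- peak_list(paste0("GP", 1:7), spec$peaks$center, rep(0.15, 7))
  bs <- run_batch(dir, analytes)
  expect_equal(bs$n_samples, 5L)
  expect_equal(bs$failed$sample, "corrupt")

  empty <- withr::local_tempdir()
  writeLines("0.5\tjunk\n1.0\t2.0", file.path(empty, "only.tsv"))
  expect_error(run_batch(empty, analytes), "no sample processed")
})

test_that("failed calibration excludes a sample from aggregation", {
  dir <- withr::local_tempdir()
  spec <- write_replicate_dir(dir, n = 3, seed = 40)
  # one extra trace without calibrant peaks: calibration must reject it
  flat <- chromatogram(seq(11, 25, by = 0.01),
                       rep(2, length(seq(11, 25, by = 0.01))) +
                         0.05 * seq(11, 25, by = 0.01))
  write_chromatogram(flat, file.path(dir, "blank.tsv"))
  analytes <- peak_list(paste0("GP", 1:7), spec$peaks$center, rep(0.15, 7))
  cal <- peak_list(paste0("c", 1:4), spec$peaks$center[c(1, 2, 5, 7)],
                   rep(0.3, 4))
  bs <- run_batch(dir, analytes, calibrants = cal)
  expect_equal(bs$n_samples, 3L)
  expect_equal(bs$failed$sample, "blank")
  expect_match(bs$failed$reason, "calibration failed")
})

test_that("compute_fab_glycosylation implements the ratio of ratios", {
  expect_equal(compute_fab_glycosylation(1, 1, 1, 1), 100)
  expect_equal(compute_fab_glycosylation(0.2, 1, 0.5, 0.5), 20)
  # scaling both G2S2 terms leaves the result unchanged
  expect_equal(compute_fab_glycosylation(0.06, 0.3, 0.4, 0.36),
               compute_fab_glycosylation(0.06 * 7, 0.3 * 7, 0.4, 0.36))
  expect_error(compute_fab_glycosylation(0, 1, 1, 1), "> 0")
  expect_error(compute_fab_glycosylation(1, 1, -2, 1), "> 0")
})

test_that("overlay export normalizes every trace to 1", {
  spec <- example_profile_spec(seed = 5)
  reps <- simulate_replicates(spec, 2, area_cv = 0.01, shift_sd = 0)
  p <- withr::local_tempfile(fileext = ".pdf")
  export_overlay(reps, p, region = c(11, 25))
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_error(export_overlay(list(flat_chromatogram(-1, 50)),
                              withr::local_tempfile(fileext = ".pdf")),
               "normalize")
})

test_that("config files round-trip through read_config", {
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# example", "start_tr = 5.0", "end_tr = 30.0",
               "min_sn = 27", "cutoff_fraction = 0.01",
               "subtract_background = true"), p)
  cfg <- read_config(p)
  expect_equal(cfg$start_tr, 5)
  expect_equal(cfg$end_tr, 30)
  expect_equal(cfg$min_sn, 27)
  expect_true(cfg$subtract_background)
  expect_equal(cfg$baseline_points, 100L) # untouched default

  writeLines("nonsense_key = 1", p)
  expect_error(read_config(p), "unknown config key")
  writeLines("min_sn = soft", p)
  expect_error(read_config(p), "non-numeric")
  expect_error(processing_config(start_tr = 10, end_tr = 5), "start_tr")

  # shipped example configs load cleanly
  for (f in list.files(system.file("extdata", package = "chromaquant"),
                       pattern = "\\.cfg$", full.names = TRUE)) {
    expect_s3_class(read_config(f), "processing_config")
  }
})
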