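# Batch orchestration: calibrate -> quantify over a folder of
# chromatograms, replicate aggregation, derived metrics and overlay export.

.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_results_tsv <- function(res, path) {
  hdr <- paste(c("name", "area_abs", "area_rel", "background", "noise",
                 "sn", "rt_residual", "gpq", "flag"), collapse = "\t")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   res$name, .fmt(res$area_abs), .fmt(res$area_rel),
                   .fmt(res$background), .fmt(res$noise), .fmt(res$sn),
                   .fmt(res$rt_residual), .fmt(res$gpq), res$flag)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Process a folder of chromatograms
#'
#' Reads every supported chromatogram file in `input_dir`, optionally
#' calibrates each against `calibrants`, quantifies the `analytes`, writes a
#' per-sample result TSV to `out_dir`, and aggregates the relative areas of
#' the successful samples into per-analyte mean, standard deviation and
#' coefficient of variation. A sample whose calibration or quantitation
#' fails is recorded under `failed` and skipped; it never aborts the batch.
#'
#' @param input_dir Directory of `.txt` / `.arw` / `.tsv` chromatograms.
#' @param analytes A [peak_list()] of analytes to quantify.
#' @param calibrants Optional [peak_list()] of calibrants; `NULL` skips
#'   retention-time calibration.
#' @param config A [processing_config()].
#' @param out_dir Output directory for per-sample TSVs (and the summary);
#'   `NULL` writes nothing.
#' @return A list of class `batch_summary`: `summary` (data.frame with
#'   `name`, `mean_area_rel`, `sd_area_rel`, `cv_pct`, `n`), `n_samples`
#'   (successful), `failed` (data.frame: sample, reason), `results` (named
#'   list of per-sample `analyte_results`).
#' @export
run_batch <- function(input_dir, analytes, calibrants = NULL,
                      config = processing_config(), out_dir = NULL) {
  stopifnot(inherits(analytes, "peak_list"))
  files <- list.files(input_dir, pattern = "\\.(txt|arw|tsv)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no chromatogram files in %s", input_dir), call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list()
  failed <- data.frame(sample = character(), reason = character())
  for (f in sort(files)) {
    id <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      ch <- read_chromatogram(f)
      if (!is.null(calibrants)) {
        ch <- calibrate(ch, calibrants, min_sn = config$min_sn,
                        min_calibrants = config$min_calibrants)$chromatogram
      }
      quantify_chromatogram(ch, analytes, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- rbind(failed,
                      data.frame(sample = id, reason = conditionMessage(res)))
      next
    }
    results[[id]] <- res
    if (!is.null(out_dir)) {
      write_results_tsv(res, file.path(out_dir, paste0(id, "_results.tsv")))
    }
  }
  if (length(results) == 0L) {
    stop(sprintf("batch failed: no sample processed successfully (%s)",
                 paste(sprintf("%s: %s", failed$sample, failed$reason),
                       collapse = "; ")), call. = FALSE)
  }
  summary <- aggregate_results(results)
  if (!is.null(out_dir)) {
    hdr <- paste(c("name", "mean_area_rel", "sd_area_rel", "cv_pct", "n"),
                 collapse = "\t")
    lines <- sprintf("%s\t%s\t%s\t%s\t%d", summary$name,
                     .fmt(summary$mean_area_rel), .fmt(summary$sd_area_rel),
                     .fmt(summary$cv_pct), summary$n)
    writeLines(c(hdr, lines), file.path(out_dir, "batch_summary.tsv"))
  }
  structure(list(summary = summary, n_samples = length(results),
                 failed = failed, results = results),
            class = "batch_summary")
}

#' Aggregate per-sample results into replicate statistics
#'
#' @param results Named list of `analyte_results` data.frames.
#' @return A data.frame with per-analyte `mean_area_rel`, `sd_area_rel`,
#'   `cv_pct` (`100 * sd / mean`, reported only when the mean is positive
#'   and n >= 2) and `n` (samples in which the analyte was quantified).
#' @export
aggregate_results <- function(results) {
  stopifnot(length(results) >= 1L)
  names_all <- unique(unlist(lapply(results, function(r) r$name)))
  rows <- lapply(names_all, function(nm) {
    vals <- unlist(lapply(results, function(r) {
      v <- r$area_rel[r$name == nm & r$flag == "ok"]
      v[!is.na(v)]
    }))
    n <- length(vals)
    m <- if (n) mean(vals) else NA_real_
    s <- if (n >= 2L) stats::sd(vals) else NA_real_
    cv <- if (n >= 2L && !is.na(m) && m > 0) 100 * s / m else NA_real_
    data.frame(name = nm, mean_area_rel = m, sd_area_rel = s, cv_pct = cv,
               n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %d sample(s), %d failed\n",
              x$n_samples, nrow(x$failed)))
  print(x$summary)
  invisible(x)
}

#' Fab glycosylation percentage
#'
#' Derived metric combining relative abundances of the G2S2 glycan group
#' (sum of the GP21-GP24 peaks) measured on the total antibody and on the
#' Fab fragment with the G1F group (GP8 + GP9 on the total antibody; Fc
#' value from glycopeptide data):
#' `100 * (G2S2_total / G2S2_fab) / (G1F_total / G1F_fc)`.
#'
#' @param g2s2_total,g2s2_fab,g1f_total,g1f_fc Positive fractions (or
#'   percentages, as long as units are consistent within each ratio).
#' @return Fab glycosylation in percent.
#' @export
#' @examples
#' compute_fab_glycosylation(0.05, 0.25, 0.3, 0.3) # 20
compute_fab_glycosylation <- function(g2s2_total, g2s2_fab, g1f_total,
                                      g1f_fc) {
  vals <- c(g2s2_total, g2s2_fab, g1f_total, g1f_fc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all glycan fractions must be finite and > 0", call. = FALSE)
  }
  100 * (g2s2_total / g2s2_fab) / (g1f_total / g1f_fc)
}

#' Export a normalized overlay plot
#'
#' Writes a static overlay of max-normalized chromatograms: each trace is
#' divided by its maximum intensity inside `region` so replicate profiles
#' superimpose.
#'
#' @param chromatograms A list of [chromatogram()]s.
#' @param path Output path; the extension selects the device (`.pdf`
#'   recommended; `.png` where a bitmap device is available).
#' @param region Optional length-2 interval (minutes) for cropping and
#'   normalization; default full range of each trace.
#' @return `path`, invisibly.
#' @export
export_overlay <- function(chromatograms, path, region = NULL) {
  stopifnot(length(chromatograms) >= 1L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 900, height = 500)
  else grDevices::pdf(path, width = 9, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  traces <- lapply(chromatograms, function(ch) {
    stopifnot(inherits(ch, "chromatogram"))
    if (!is.null(region)) ch <- crop_chromatogram(ch, region[1], region[2])
    m <- max(ch$intensity)
    if (m <= 0) stop("cannot normalize a non-positive trace", call. = FALSE)
    list(time = ch$time, y = ch$intensity / m, id = ch$sample_id)
  })
  xr <- range(unlist(lapply(traces, `[[`, "time")))
  graphics::plot(NA, xlim = xr, ylim = c(0, 1.05), xlab = "t_r (min)",
                 ylab = "normalized intensity", main = "Normalized overlay")
  cols <- grDevices::hcl.colors(max(3L, length(traces)), "Dark 3")
  for (i in seq_along(traces)) {
    graphics::lines(traces[[i]]$time, traces[[i]]$y, col = cols[i])
  }
  invisible(path)
}
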