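# Retention-time calibration against a calibrant peak list.
#
# For each calibrant the observed retention time is the highest-intensity
# data point within t_r +/- dt_r; calibrants failing a signal-to-noise
# threshold are rejected. A 2nd-degree polynomial f_p is least-squares
# fitted through the retained (observed, expected) pairs and applied to the
# whole time axis as t_new = f_p(t_original).

#' Observed retention time of a calibrant (apex data point)
#'
#' Returns the time of the maximum-intensity data point inside the window
#' `[tr - window, tr + window]`; ties break towards the earliest point.
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [peak_list()] (or a list with `tr`, `window`).
#' @return Observed retention time (minutes).
#' @export
find_observed_tr <- function(chrom, peak) {
  stopifnot(inherits(chrom, "chromatogram"))
  idx <- window_indices(chrom, peak$tr, peak$window)
  if (length(idx) == 0L) {
    stop(sprintf("calibrant window %.4g +/- %.4g contains no data points",
                 peak$tr, peak$window), call. = FALSE)
  }
  chrom$time[idx[which.max(chrom$intensity[idx])]]
}

#' Calibrate the retention-time axis
#'
#' Locates each calibrant's observed apex, gates calibrants on
#' signal-to-noise, fits `expected = f_p(observed)` with a 2nd-degree
#' polynomial when at least `min_calibrants` survive, and maps the whole
#' time axis through `f_p`. A fit that is non-monotone over the data range
#' (so the new time axis would fold back on itself) is treated as failure.
#'
#' @param chrom A [chromatogram()].
#' @param calibrants A [peak_list()] whose `tr` are the expected (reference)
#'   retention times and whose windows bound the search for the observed
#'   apex.
#' @param min_sn Minimum signal-to-noise for a calibrant to be retained
#'   (default 9).
#' @param min_calibrants Minimum number of retained calibrants (>= 3 for a
#'   degree-2 fit; default 4).
#' @param noise Optional `noise_estimate`; estimated from the whole
#'   chromatogram when `NULL`.
#' @return A list with `chromatogram` (time axis replaced by
#'   `f_p(time)`) and `result`, a `calibration_result` holding
#'   `coefficients` (ascending degree), `used` (data.frame: name, observed,
#'   expected, sn) and `rejected` (data.frame: name, reason).
#' @export
calibrate <- function(chrom, calibrants, min_sn = 9, min_calibrants = 4L,
                      noise = NULL) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(calibrants, "peak_list"))
  min_calibrants <- as.integer(min_calibrants)
  if (min_calibrants < 3L) {
    stop("min_calibrants must be >= 3 for a degree-2 polynomial",
         call. = FALSE)
  }
  if (is.null(noise)) {
    noise <- estimate_background_noise(
      chrom, window_points = min(100L, length(chrom) %/% 2L))
  }
  used <- data.frame(name = character(), observed = numeric(),
                     expected = numeric(), sn = numeric())
  rejected <- data.frame(name = character(), reason = character())
  for (i in seq_len(nrow(calibrants))) {
    pk <- calibrants[i, ]
    obs <- tryCatch(find_observed_tr(chrom, pk), error = function(e) NA_real_)
    if (is.na(obs)) {
      rejected <- rbind(rejected,
                        data.frame(name = pk$name, reason = "window empty"))
      next
    }
    sn <- signal_to_noise(chrom, pk, noise)
    if (sn < min_sn) {
      rejected <- rbind(rejected, data.frame(
        name = pk$name,
        reason = sprintf("S/N %.3g below threshold %.3g", sn, min_sn)))
      next
    }
    used <- rbind(used, data.frame(name = pk$name, observed = obs,
                                   expected = pk$tr, sn = sn))
  }
  if (nrow(used) < min_calibrants) {
    stop(sprintf(
      "calibration failed: %d of %d calibrants retained (min %d); rejected: %s",
      nrow(used), nrow(calibrants), min_calibrants,
      if (nrow(rejected)) paste(sprintf("%s (%s)", rejected$name,
                                        rejected$reason), collapse = "; ")
      else "none"), call. = FALSE)
  }
  X <- cbind(1, used$observed, used$observed^2)
  coefs <- unname(stats::lm.fit(X, used$expected)$coefficients)
  new_time <- polyval(coefs, chrom$time)
  if (any(diff(new_time) <= 0)) {
    stop(paste("calibration failed: fitted polynomial is non-monotone over",
               "the data range"), call. = FALSE)
  }
  result <- structure(list(coefficients = coefs, used = used,
                           rejected = rejected),
                      class = "calibration_result")
  list(chromatogram = chromatogram(new_time, chrom$intensity,
                                   sample_id = chrom$sample_id,
                                   source_path = chrom$source_path,
                                   dialect = chrom$dialect),
       result = result)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> f_p(t) = %.6g + %.6g t + %.6g t^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  %d calibrants used, %d rejected\n",
              nrow(x$used), nrow(x$rejected)))
  invisible(x)
}
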