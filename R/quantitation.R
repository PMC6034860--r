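# Integration-based peak quantitation.
#
# The absolute area of an analyte is the rectangle-rule sum
# A_p = sum_i t_m * (I_i - background) over the data points in the closed
# window [t_r - dt_r, t_r + dt_r], where t_m is the sampling interval.
# Background and noise are estimated locally, from the lowest-average run of
# points within +/- background_window of the analyte.

#' Integrate an analyte window
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [peak_list()] (or a list with `tr`, `window`).
#' @param background Constant background level subtracted from every point
#'   (default 0). Negative point contributions are retained.
#' @return Absolute area `A_p` in signal x minutes.
#' @export
#' @examples
#' ch <- chromatogram(seq(0, 1, by = 0.1), rep(10, 11))
#' integrate_peak(ch, list(tr = 0.5, window = 0.2)) # 5 points x 0.1 x 10
integrate_peak <- function(chrom, peak, background = 0) {
  stopifnot(inherits(chrom, "chromatogram"))
  idx <- window_indices(chrom, peak$tr, peak$window)
  if (length(idx) == 0L) {
    stop(sprintf("analyte window %.4g +/- %.4g contains no data points",
                 peak$tr, peak$window), call. = FALSE)
  }
  tm <- if (length(idx) >= 2L) stats::median(diff(chrom$time[idx]))
        else sampling_interval(chrom)
  sum(tm * (chrom$intensity[idx] - background))
}

#' Quantify all analytes of a chromatogram
#'
#' For every analyte window: estimate the local background and noise from
#' the lowest-average run of points within `background_window` of the
#' analyte, integrate the background-subtracted window, and attach the three
#' QC criteria (signal-to-noise, residual retention time, Gaussian peak
#' quality). Relative areas are absolute areas divided by the summed
#' absolute area of all successfully quantified analytes.
#'
#' @param chrom A (calibrated) [chromatogram()].
#' @param analytes A [peak_list()].
#' @param config A [processing_config()]; `background_window` sets the
#'   half-width (minutes) of the region searched for the local background,
#'   and `subtract_background` (default `TRUE`) controls whether the area is
#'   background-subtracted.
#' @return A data.frame of class `analyte_results` with one row per analyte:
#'   `name`, `area_abs`, `area_rel`, `background`, `noise`, `sn`,
#'   `rt_residual`, `gpq`, `flag` (`"ok"` or a reason the analyte was
#'   excluded). Flagged analytes have `NA` areas and do not enter the
#'   relative-area denominator.
#' @export
quantify_chromatogram <- function(chrom, analytes,
                                  config = processing_config()) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(analytes, "peak_list"))
  n <- nrow(analytes)
  if (n == 0L) stop("empty analyte list", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pk <- analytes[i, ]
    idx <- window_indices(chrom, pk$tr, pk$window)
    if (length(idx) < 2L) {
      rows[[i]] <- data.frame(
        name = pk$name, area_abs = NA_real_, area_rel = NA_real_,
        background = NA_real_, noise = NA_real_, sn = NA_real_,
        rt_residual = NA_real_, gpq = NA_real_, flag = "window outside data")
      next
    }
    # local noise window: as many points as span the analyte window itself,
    # searched over +/- background_window around the analyte
    wp <- max(10L, length(idx))
    region <- c(pk$tr - pk$window - config$background_window,
                pk$tr + pk$window + config$background_window)
    ne <- tryCatch(
      estimate_background_noise(chrom, region, wp),
      error = function(e) estimate_background_noise(
        chrom, range(chrom$time), min(wp, length(chrom) %/% 2L)))
    bg <- if (isTRUE(config$subtract_background)) ne$background else 0
    area <- integrate_peak(chrom, pk, background = bg)
    sn <- if (ne$noise > 0) signal_to_noise(chrom, pk, ne) else NA_real_
    rt <- tryCatch(residual_retention_time(chrom, pk),
                   error = function(e) NA_real_)
    gpq <- tryCatch(gaussian_peak_quality(chrom, pk, ne),
                    error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      name = pk$name, area_abs = area, area_rel = NA_real_,
      background = ne$background, noise = ne$noise, sn = sn,
      rt_residual = rt, gpq = gpq, flag = "ok")
  }
  res <- do.call(rbind, rows)
  ok <- res$flag == "ok"
  total <- sum(res$area_abs[ok])
  if (any(ok)) {
    if (total <= 0) {
      stop("total absolute area is non-positive; cannot form relative areas",
           call. = FALSE)
    }
    res$area_rel[ok] <- res$area_abs[ok] / total
  }
  rownames(res) <- NULL
  class(res) <- c("analyte_results", "data.frame")
  attr(res, "sample_id") <- chrom$sample_id
  res
}
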