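# Per-analyte quality-control criteria: residual retention time,
# signal-to-noise and Gaussian peak quality.

# continuous argmax of an interpolating spline through the window points:
# dense evaluation at 10x the sampling resolution, then local refinement
.spline_argmax <- function(t, y) {
  f <- stats::splinefun(t, y, method = "natural")
  grid <- seq(t[1], t[length(t)], length.out = max(10L * length(t), 100L))
  g <- f(grid)
  i <- which.max(g)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (hi - lo <= 0) return(grid[i])
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  opt$maximum
}

#' Observed retention time of an analyte (spline apex)
#'
#' Fits an interpolating univariate spline through all data points in the
#' analyte window and returns the time of its continuous maximum, giving
#' sub-sampling-interval apex resolution.
#'
#' @param chrom A [chromatogram()].
#' @param tr,window Window center and half-width (minutes).
#' @return Observed retention time (minutes).
#' @export
observed_tr_spline <- function(chrom, tr, window) {
  stopifnot(inherits(chrom, "chromatogram"))
  idx <- window_indices(chrom, tr, window)
  if (length(idx) < 4L) {
    stop(sprintf("analyte window %.4g +/- %.4g holds %d points; >= 4 needed",
                 tr, window, length(idx)), call. = FALSE)
  }
  .spline_argmax(chrom$time[idx], chrom$intensity[idx])
}

#' Residual retention time
#'
#' `r_t = |t_r(obs) - t_r(exp)|` where the observed retention time is the
#' continuous maximum of an interpolating spline through the window points.
#' Small values indicate good calibration; large values flag drifting or
#' misassigned peaks.
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [peak_list()] (or any list with `tr`, `window`).
#' @return Nonnegative residual (minutes).
#' @export
residual_retention_time <- function(chrom, peak) {
  abs(observed_tr_spline(chrom, peak$tr, peak$window) - peak$tr)
}

#' Signal-to-noise ratio of an analyte window
#'
#' `(max window intensity - background) / noise`, with background and noise
#' from the lowest-average sliding window (see
#' [estimate_background_noise()]).
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [peak_list()].
#' @param noise A `noise_estimate`.
#' @return Signal-to-noise ratio (unitless; may be negative for windows
#'   below the background).
#' @export
signal_to_noise <- function(chrom, peak, noise) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!is.finite(noise$noise) || noise$noise <= 0) {
    stop("noise estimate is zero; use a larger noise window", call. = FALSE)
  }
  idx <- window_indices(chrom, peak$tr, peak$window)
  if (length(idx) == 0L) {
    stop(sprintf("window %.4g +/- %.4g contains no data points",
                 peak$tr, peak$window), call. = FALSE)
  }
  (max(chrom$intensity[idx]) - noise$background) / noise$noise
}

#' Gaussian peak quality
#'
#' Subtracts the background from every window point, fits a single Gaussian
#' to the background-subtracted points and returns the ratio of the analytic
#' area of that Gaussian (`A * sigma * sqrt(2*pi)`) to the
#' background-subtracted integrated area. Values near 1 indicate a clean
#' Gaussian peak; tailing, fronting or overlapping peaks push the ratio away
#' from 1.
#'
#' @param chrom A [chromatogram()].
#' @param peak One row of a [peak_list()].
#' @param noise A `noise_estimate` supplying the background.
#' @return The GPQ ratio, or `NA` when the Gaussian fit fails.
#' @export
gaussian_peak_quality <- function(chrom, peak, noise) {
  stopifnot(inherits(chrom, "chromatogram"))
  idx <- window_indices(chrom, peak$tr, peak$window)
  if (length(idx) < 4L) {
    stop(sprintf("window %.4g +/- %.4g holds %d points; >= 4 needed",
                 peak$tr, peak$window, length(idx)), call. = FALSE)
  }
  t <- chrom$time[idx]
  y <- chrom$intensity[idx] - noise$background
  tm <- stats::median(diff(t))
  a_int <- sum(tm * y)
  if (!is.finite(a_int) || a_int == 0) return(NA_real_)
  fit <- fit_gaussian(t, y, baseline = 0, sigma_min = tm / 2,
                      sigma_max = 2 * diff(range(t)))
  if (is.null(fit)) return(NA_real_)
  gauss_area(fit$amplitude, fit$sigma) / a_int
}
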