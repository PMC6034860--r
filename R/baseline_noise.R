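# Background and noise estimation, baseline fitting/subtraction.

#' Estimate background and noise from the lowest-average window
#'
#' Slides a window of `window_points` consecutive data points over `region`
#' and selects the window with the lowest mean intensity; the background is
#' that mean and the noise is the standard deviation of the same window.
#' Ties are broken towards the earliest window.
#'
#' @param chrom A [chromatogram()].
#' @param region Numeric length-2 interval (minutes) to search; defaults to
#'   the full time range.
#' @param window_points Number of consecutive points per window (>= 2).
#' @return A list of class `noise_estimate` with elements `background`,
#'   `noise` (sample standard deviation), `window_start` (minutes) and
#'   `window_points`.
#' @export
#' @examples
#' ch <- chromatogram(seq(0, 10, by = 0.01), rnorm(1001, mean = 3))
#' estimate_background_noise(ch, window_points = 50)
estimate_background_noise <- function(chrom, region = NULL,
                                      window_points = 100L) {
  stopifnot(inherits(chrom, "chromatogram"))
  window_points <- as.integer(window_points)
  if (window_points < 2L) stop("window_points must be >= 2", call. = FALSE)
  if (is.null(region)) region <- range(chrom$time)
  idx <- which(chrom$time >= region[1] & chrom$time <= region[2])
  n <- length(idx)
  if (n < window_points) {
    stop(sprintf("region holds %d points; %d needed for the noise window",
                 n, window_points), call. = FALSE)
  }
  y <- chrom$intensity[idx]
  w <- window_points
  cs <- cumsum(c(0, y))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  best <- which.min(means) # which.min returns the first minimum: earliest wins
  run <- y[best:(best + w - 1)]
  structure(
    list(background = mean(run), noise = stats::sd(run),
         window_start = chrom$time[idx[best]], window_points = w),
    class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> background = %.6g, noise = %.6g (%d points from t = %.4g)\n",
    x$background, x$noise, x$window_points, x$window_start))
  invisible(x)
}

#' Fit a low-order baseline polynomial
#'
#' Partitions `region` into consecutive blocks of `window_points` data points,
#' takes the minimum-intensity point of each block as a baseline support
#' point, and least-squares fits a polynomial of degree `order` through the
#' support points.
#'
#' @param chrom A [chromatogram()].
#' @param region Numeric length-2 interval (minutes); defaults to full range.
#' @param order Polynomial degree, one of 0, 1, 2.
#' @param window_points Block size in data points.
#' @return Numeric coefficient vector in ascending degree order
#'   (intercept first), length `order + 1`.
#' @export
fit_baseline <- function(chrom, region = NULL, order = 1L,
                         window_points = 100L) {
  stopifnot(inherits(chrom, "chromatogram"))
  order <- as.integer(order)
  if (!order %in% 0:2) stop("baseline order must be 0, 1 or 2", call. = FALSE)
  if (is.null(region)) region <- range(chrom$time)
  idx <- which(chrom$time >= region[1] & chrom$time <= region[2])
  n <- length(idx)
  nblock <- n %/% as.integer(window_points)
  if (nblock < order + 1L) {
    stop(sprintf(
      "only %d baseline support points for a degree-%d fit (need %d)",
      nblock, order, order + 1L), call. = FALSE)
  }
  sup_t <- numeric(nblock)
  sup_y <- numeric(nblock)
  for (b in seq_len(nblock)) {
    blk <- idx[((b - 1L) * window_points + 1L):(b * window_points)]
    j <- blk[which.min(chrom$intensity[blk])]
    sup_t[b] <- chrom$time[j]
    sup_y[b] <- chrom$intensity[j]
  }
  if (order == 0L) return(mean(sup_y))
  X <- stats::poly(sup_t, degree = order, raw = TRUE, simple = TRUE)
  fit <- stats::lm.fit(cbind(1, X), sup_y)
  unname(fit$coefficients)
}

#' Subtract a polynomial baseline
#'
#' Evaluates the polynomial at every time point and subtracts it from the
#' intensity. Negative intensities are retained.
#'
#' @param chrom A [chromatogram()].
#' @param coefficients Ascending-degree polynomial coefficients as returned
#'   by [fit_baseline()].
#' @return A baseline-subtracted [chromatogram()].
#' @export
subtract_baseline <- function(chrom, coefficients) {
  stopifnot(inherits(chrom, "chromatogram"))
  chromatogram(chrom$time, chrom$intensity - polyval(coefficients, chrom$time),
               sample_id = chrom$sample_id, source_path = chrom$source_path,
               dialect = chrom$dialect)
}
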