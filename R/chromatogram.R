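#' chromaquant: batch processing and quantitation of HPLC-FD chromatograms
#'
#' Tools for automated processing of 2D (retention time vs. fluorescence
#' intensity) chromatograms: text-format import, background/noise estimation,
#' first-derivative spline peak detection with iterative Gaussian
#' fit-and-subtract, polynomial retention-time calibration, integration-based
#' quantitation, quality-control metrics and replicate batch statistics.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a chromatogram
#'
#' A chromatogram pairs a strictly increasing retention-time vector (minutes)
#' with an equal-length intensity vector (arbitrary fluorescence units).
#'
#' @param time Numeric vector of retention times in minutes, strictly
#'   increasing, length >= 2, all finite.
#' @param intensity Numeric vector of signal intensities, same length as
#'   `time`. May be negative (e.g. after baseline subtraction).
#' @param sample_id Sample identifier; defaults to `"sample"`.
#' @param source_path Path the data came from, or `NA`.
#' @param dialect One of `"plain_tsv"`, `"chromeleon_txt"`, `"empower_arw"`,
#'   or `NA` for in-memory data.
#' @return An object of class `chromatogram`.
#' @export
#' @examples
#' ch <- chromatogram(seq(0, 1, by = 0.1), rnorm(11))
#' sampling_interval(ch)
chromatogram <- function(time, intensity, sample_id = "sample",
                         source_path = NA_character_, dialect = NA_character_) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a chromatogram needs at least 2 data points", call. = FALSE)
  }
  if (!all(is.finite(time))) stop("non-finite time values", call. = FALSE)
  if (!all(is.finite(intensity))) {
    stop("non-finite intensity values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time vector must be strictly increasing", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), time = time,
         intensity = intensity, source_path = source_path, dialect = dialect),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %s: %d points, t = [%.4g, %.4g] min, t_m = %.4g min\n",
    x$sample_id, length(x$time), x$time[1], x$time[length(x$time)],
    sampling_interval(x)))
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$time)

#' Sampling interval of a chromatogram
#'
#' The time needed to measure one data point, `t_m`, taken as the median of
#' successive time differences (robust to occasional dropped scans).
#'
#' @param chrom A [chromatogram()].
#' @return Sampling interval in minutes.
#' @export
sampling_interval <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  stats::median(diff(chrom$time))
}

#' Restrict a chromatogram to a time interval
#'
#' @param chrom A [chromatogram()].
#' @param start,end Interval bounds in minutes (closed interval).
#' @return A `chromatogram` containing the points with
#'   `start <= time <= end`.
#' @export
crop_chromatogram <- function(chrom, start, end) {
  stopifnot(inherits(chrom, "chromatogram"), start < end)
  keep <- chrom$time >= start & chrom$time <= end
  if (sum(keep) < 2L) {
    stop(sprintf("fewer than 2 data points in [%g, %g]", start, end),
         call. = FALSE)
  }
  chromatogram(chrom$time[keep], chrom$intensity[keep],
               sample_id = chrom$sample_id, source_path = chrom$source_path,
               dialect = chrom$dialect)
}

#' Construct a peak definition table
#'
#' A peak list names analyte (or calibrant) windows: for each peak a name,
#' the expected retention time `tr` and the half-window `window` so that
#' the quantitation window is `[tr - window, tr + window]`.
#'
#' @param name Character vector of peak names.
#' @param tr Expected retention times (minutes), all > 0.
#' @param window Half-window widths (minutes), all > 0.
#' @return A `data.frame` with class `peak_list` and columns
#'   `name`, `tr`, `window`.
#' @export
peak_list <- function(name, tr, window) {
  name <- as.character(name)
  tr <- as.numeric(tr)
  window <- as.numeric(window)
  n <- length(name)
  if (length(tr) != n || length(window) != n) {
    stop("name, tr and window must have equal length", call. = FALSE)
  }
  if (n > 0L && (any(!is.finite(tr)) || any(tr <= 0))) {
    stop("expected retention times must be finite and > 0", call. = FALSE)
  }
  if (n > 0L && (any(!is.finite(window)) || any(window <= 0))) {
    stop("peak windows must be finite and > 0", call. = FALSE)
  }
  structure(data.frame(name = name, tr = tr, window = window,
                       stringsAsFactors = FALSE),
            class = c("peak_list", "data.frame"))
}

# evaluate a polynomial with ascending coefficients (c0, c1, c2, ...)
polyval <- function(coef, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

# indices of points inside the closed window [tr - w, tr + w]; a relative
# epsilon keeps grid points on the boundary from falling out through
# floating-point noise
window_indices <- function(chrom, tr, window) {
  eps <- sqrt(.Machine$double.eps) * max(abs(tr) + window, 1)
  which(chrom$time >= tr - window - eps & chrom$time <= tr + window + eps)
}
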