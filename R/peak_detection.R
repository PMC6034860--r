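# First-derivative spline peak detection with iterative Gaussian
# fit-and-subtract (FOD-GPD).
#
# Each iteration fits a univariate spline to the current residual signal,
# locates the local maxima/minima of its first derivative, brackets the
# apex of the highest remaining data point between a derivative maximum and
# the following derivative minimum, fits a Gaussian to the raw residual data
# inside the bracket (above the constant background), subtracts it, and
# repeats until the highest residual point falls below a fraction of the
# initial (background-subtracted) maximum.

#' Detection settings for FOD-GPD
#'
#' @param region Numeric length-2 time interval (minutes) to scan.
#' @param cutoff_fraction Stop once the highest background-subtracted
#'   residual intensity drops below this fraction of the initial maximum;
#'   strictly between 0 and 1. Default 0.01 (1 percent).
#' @param max_iterations Hard iteration cap guarding against pathological
#'   non-Gaussian signals. Default 50.
#' @param spline_smoothing Smoothing for the bracket spline: `NULL`
#'   (default) selects the penalty by generalized cross-validation; a
#'   positive number requests a smoothing spline whose residual sum of
#'   squares matches it (the classic `n * noise^2` target); `0` forces an
#'   interpolating spline.
#' @return A list of class `detection_settings`.
#' @export
detection_settings <- function(region, cutoff_fraction = 0.01,
                               max_iterations = 50L,
                               spline_smoothing = NULL) {
  stopifnot(length(region) == 2L, region[1] < region[2])
  if (!(cutoff_fraction > 0 && cutoff_fraction < 1)) {
    stop("cutoff_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  structure(list(region = as.numeric(region),
                 cutoff_fraction = cutoff_fraction,
                 max_iterations = as.integer(max_iterations),
                 spline_smoothing = spline_smoothing),
            class = "detection_settings")
}

# local maxima / minima indices of a numeric sequence (earliest wins on ties)
.local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(max = integer(), min = integer()))
  i <- 2:(n - 1L)
  list(max = i[v[i] > v[i - 1L] & v[i] >= v[i + 1L]],
       min = i[v[i] < v[i - 1L] & v[i] <= v[i + 1L]])
}

#' Candidate peak brackets from the first derivative of a spline
#'
#' Fits a univariate spline to the signal inside `settings$region`, computes
#' its first derivative at the data points, and pairs every local maximum of
#' the derivative with the next local minimum after it. Each resulting time
#' interval brackets one candidate apex (roughly the mean +/- one standard
#' deviation of a Gaussian peak).
#'
#' @param chrom A [chromatogram()].
#' @param settings A [detection_settings()].
#' @return A data.frame with columns `lo`, `hi` (minutes); zero rows when
#'   the derivative has no usable extrema (e.g. a flat signal).
#' @export
derivative_brackets <- function(chrom, settings) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(settings, "detection_settings"))
  idx <- which(chrom$time >= settings$region[1] &
                 chrom$time <= settings$region[2])
  if (length(idx) < 10L) {
    stop("need at least 10 data points in the detection region",
         call. = FALSE)
  }
  t <- chrom$time[idx]
  y <- chrom$intensity[idx]
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(1, abs(max(y)))) {
    return(data.frame(lo = numeric(), hi = numeric()))
  }
  spl <- tryCatch(fit_signal_spline(t, y, settings$spline_smoothing),
                  error = function(e)
                    stop("spline fit failed: ", conditionMessage(e),
                         call. = FALSE))
  d1 <- spl(t, deriv = 1)
  ex <- .local_extrema(d1)
  # drop numerically negligible wiggles (flat tails of noiseless signals)
  thr <- 1e-6 * max(abs(d1))
  ex$max <- ex$max[abs(d1[ex$max]) > thr]
  ex$min <- ex$min[abs(d1[ex$min]) > thr]
  if (length(ex$max) == 0L || length(ex$min) == 0L) {
    return(data.frame(lo = numeric(), hi = numeric()))
  }
  lo <- numeric(0); hi <- numeric(0)
  mins <- ex$min
  for (m in ex$max) {
    nxt <- mins[mins > m]
    if (length(nxt) == 0L) next
    lo <- c(lo, t[m]); hi <- c(hi, t[nxt[1]])
  }
  data.frame(lo = lo, hi = hi)
}

#' Detect peaks by iterative Gaussian fit-and-subtract
#'
#' Runs the FOD-GPD loop on the signal inside `settings$region`: bracket
#' candidate apexes via [derivative_brackets()], Gaussian-fit the bracket
#' holding the highest residual data point (above `noise$background`),
#' subtract the fitted Gaussian from the residual over the whole region, and
#' repeat while the highest background-subtracted residual stays at or above
#' `cutoff_fraction` times the initial background-subtracted maximum.
#' Residuals may go negative; they are not clipped, so the total signal area
#' is conserved between fitted peaks and final residual.
#'
#' @param chrom A [chromatogram()].
#' @param settings A [detection_settings()].
#' @param noise A `noise_estimate` from [estimate_background_noise()]; its
#'   background serves as the constant baseline for every Gaussian fit. When
#'   `NULL` it is estimated from the detection region with the default
#'   window.
#' @return A data.frame of class `detected_peaks`, sorted by center, with
#'   columns `center`, `sigma`, `amplitude`, `fwhm`, `area` (analytic
#'   Gaussian area), `bracket_lo`, `bracket_hi`, `iteration`; attributes
#'   `residual` (chromatogram of what remains), `truncated` (`TRUE` when the
#'   iteration cap stopped the loop) and `initial_max`.
#' @export
detect_peaks <- function(chrom, settings, noise = NULL) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(settings, "detection_settings"))
  if (is.null(noise)) {
    noise <- estimate_background_noise(chrom, settings$region,
                                       min(100L, length(chrom) %/% 2L))
  }
  idx <- which(chrom$time >= settings$region[1] &
                 chrom$time <= settings$region[2])
  if (is.null(settings$spline_smoothing) && noise$noise > 0) {
    # default smoothing target: n * noise^2 (classic smoothing-spline rule)
    settings$spline_smoothing <- length(idx) * noise$noise^2
  }
  t <- chrom$time[idx]
  y <- chrom$intensity[idx]
  tm <- stats::median(diff(t))
  bg <- noise$background

  init_max <- max(y - bg)
  cutoff <- settings$cutoff_fraction * init_max
  masked <- rep(FALSE, length(y))
  res <- y
  out <- list()
  iter <- 0L
  truncated <- FALSE

  while (TRUE) {
    avail <- res - bg
    avail[masked] <- -Inf
    if (max(avail) < cutoff || all(masked)) break
    if (iter >= settings$max_iterations) {
      truncated <- TRUE
      break
    }
    iter <- iter + 1L
    rc <- chromatogram(t, res, sample_id = chrom$sample_id)
    br <- derivative_brackets(rc, settings)
    if (nrow(br) == 0L) break
    apex <- which.max(avail)
    hit <- which(br$lo <= t[apex] & t[apex] <= br$hi)
    if (length(hit) == 0L) {
      masked[apex] <- TRUE
      next
    }
    b <- br[hit[1], ]
    sel <- which(t >= b$lo & t <= b$hi)
    # widen degenerate brackets so a 3-parameter fit is determined
    grow <- 1L
    while (length(sel) < 4L && grow <= length(y)) {
      sel <- which(t >= b$lo - grow * tm & t <= b$hi + grow * tm)
      grow <- grow + 1L
    }
    fit <- fit_gaussian(t[sel], res[sel], baseline = bg,
                        sigma_min = tm, sigma_max = diff(range(t[sel])))
    if (is.null(fit)) {
      masked[apex] <- TRUE
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      center = fit$center, sigma = fit$sigma, amplitude = fit$amplitude,
      fwhm = FWHM_FACTOR * fit$sigma,
      area = gauss_area(fit$amplitude, fit$sigma),
      bracket_lo = b$lo, bracket_hi = b$hi, iteration = iter)
    res <- res - gauss_shape(t, fit$amplitude, fit$center, fit$sigma)
  }

  peaks <- if (length(out)) do.call(rbind, out) else
    data.frame(center = numeric(), sigma = numeric(), amplitude = numeric(),
               fwhm = numeric(), area = numeric(), bracket_lo = numeric(),
               bracket_hi = numeric(), iteration = integer())
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("detected_peaks", "data.frame")
  attr(peaks, "residual") <- chromatogram(t, res,
                                          sample_id = chrom$sample_id)
  attr(peaks, "truncated") <- truncated
  attr(peaks, "initial_max") <- init_max
  if (truncated) {
    warning("detection stopped at max_iterations before reaching the cutoff",
            call. = FALSE)
  }
  peaks
}

#' Convert detected peaks to a quantitation peak list
#'
#' Names peaks `peak1..peakN` in retention-time order; the expected retention
#' time is the fitted Gaussian center and the half-window is half the full
#' width at half maximum.
#'
#' @param peaks A `detected_peaks` data.frame from [detect_peaks()].
#' @return A [peak_list()].
#' @export
peaks_to_definitions <- function(peaks) {
  stopifnot(inherits(peaks, "detected_peaks"))
  if (nrow(peaks) == 0L) stop("no detected peaks to convert", call. = FALSE)
  ord <- order(peaks$center)
  peak_list(sprintf("peak%d", seq_len(nrow(peaks))),
            peaks$center[ord], peaks$fwhm[ord] / 2)
}

#' Suggest evenly spaced calibrant peaks
#'
#' Partitions the detected retention-time span into `k` equal sub-spans and
#' picks the highest-amplitude peak in each; empty sub-spans fall back to the
#' next-highest-amplitude unused peak overall, so exactly `k` calibrants are
#' proposed whenever at least `k` peaks exist.
#'
#' @param peaks A `detected_peaks` data.frame.
#' @param k Number of calibrants wanted (default 4).
#' @return A [peak_list()] of the chosen peaks (named `cal1..calk` in
#'   retention-time order). With fewer than `k` peaks, all peaks are
#'   returned with a warning.
#' @export
suggest_calibrants <- function(peaks, k = 4L) {
  stopifnot(inherits(peaks, "detected_peaks"))
  k <- as.integer(k)
  n <- nrow(peaks)
  if (n == 0L) stop("no detected peaks", call. = FALSE)
  if (n < k) {
    warning(sprintf("only %d peaks available for %d calibrants", n, k),
            call. = FALSE)
    sel <- seq_len(n)
  } else {
    span <- range(peaks$center)
    edges <- seq(span[1], span[2], length.out = k + 1L)
    sel <- integer(0)
    for (q in seq_len(k)) {
      inq <- which(peaks$center >= edges[q] &
                     (peaks$center < edges[q + 1L] | q == k) &
                     !(seq_len(n) %in% sel))
      if (length(inq)) sel <- c(sel, inq[which.max(peaks$amplitude[inq])])
    }
    while (length(sel) < k) {
      left <- setdiff(seq_len(n), sel)
      sel <- c(sel, left[which.max(peaks$amplitude[left])])
    }
  }
  sel <- sel[order(peaks$center[sel])]
  peak_list(sprintf("cal%d", seq_along(sel)),
            peaks$center[sel], peaks$fwhm[sel] / 2)
}
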