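# Internal numerical helpers: smoothing/interpolating splines and
# constrained Gaussian least squares.

# Fit a univariate spline to (t, y).
#
# smoothing == 0  -> interpolating cubic spline (natural boundary).
# smoothing > 0   -> smoothing spline whose residual sum of squares is tuned
#                    (over spar) to approximate `smoothing`, mirroring the
#                    classic s = n * noise^2 heuristic.
# smoothing NULL  -> smoothing spline with GCV-selected penalty (default).
#
# Returns a function(x, deriv = 0).
fit_signal_spline <- function(t, y, smoothing = NULL) {
  if (!is.null(smoothing) && smoothing <= 0) {
    f <- stats::splinefun(t, y, method = "natural")
    return(function(x, deriv = 0) f(x, deriv = deriv))
  }
  fit <- if (is.null(smoothing)) {
    stats::smooth.spline(t, y, all.knots = TRUE, keep.data = FALSE)
  } else {
    rss_at <- function(spar) {
      s <- stats::smooth.spline(t, y, spar = spar, all.knots = TRUE,
                                keep.data = FALSE)
      sum((stats::predict(s, t)$y - y)^2)
    }
    lo <- -1.5; hi <- 1.5
    spar <- if (rss_at(lo) >= smoothing) {
      lo
    } else if (rss_at(hi) <= smoothing) {
      hi
    } else {
      stats::uniroot(function(s) rss_at(s) - smoothing, c(lo, hi),
                     tol = 0.01)$root
    }
    stats::smooth.spline(t, y, spar = spar, all.knots = TRUE,
                         keep.data = FALSE)
  }
  function(x, deriv = 0) stats::predict(fit, x, deriv = deriv)$y
}

gauss_shape <- function(t, amplitude, center, sigma) {
  amplitude * exp(-((t - center)^2) / (2 * sigma^2))
}

# Least-squares Gaussian above a fixed constant baseline.
# Bounds: amplitude > 0, sigma in (sigma_min, sigma_max), center in t-range.
# Returns NULL when the optimiser fails or lands on a degenerate solution.
fit_gaussian <- function(t, y, baseline = 0, sigma_min = NULL,
                         sigma_max = NULL) {
  if (length(t) < 4L) return(NULL)
  span <- diff(range(t))
  if (span <= 0) return(NULL)
  if (is.null(sigma_min)) sigma_min <- stats::median(diff(t)) / 2
  if (is.null(sigma_max)) sigma_max <- span
  y0 <- y - baseline
  i0 <- which.max(y0)
  a0 <- max(y0[i0], 1e-8)
  p0 <- c(A = a0, mu = t[i0], sigma = max(span / 4, sigma_min * 1.01))
  obj <- function(p) sum((y0 - gauss_shape(t, p[1], p[2], p[3]))^2)
  fit <- tryCatch(
    stats::optim(p0, obj, method = "L-BFGS-B",
                 lower = c(1e-10, t[1], sigma_min),
                 upper = c(Inf, t[length(t)], sigma_max)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  p <- fit$par
  if (p[1] <= 0 || p[3] <= 0) return(NULL)
  list(amplitude = unname(p[1]), center = unname(p[2]),
       sigma = unname(p[3]), sse = fit$value)
}

# analytic area of a Gaussian peak
gauss_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

FWHM_FACTOR <- 2 * sqrt(2 * log(2)) # 2.3548

# exponentially modified Gaussian with unit-preserving area:
# integral = amplitude * sigma * sqrt(2*pi), tau -> 0 recovers the Gaussian.
emg_shape <- function(t, amplitude, center, sigma, tau) {
  if (tau <= 0) return(gauss_shape(t, amplitude, center, sigma))
  area <- gauss_area(amplitude, sigma)
  z <- sigma / tau - (t - center) / sigma
  # log-scale evaluation avoids exp-overflow * erfc-underflow NaNs
  log_erfc <- log(2) + stats::pnorm(-z, log.p = TRUE)
  area / (2 * tau) *
    exp(sigma^2 / (2 * tau^2) - (t - center) / tau + log_erfc)
}
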