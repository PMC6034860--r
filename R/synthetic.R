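# Seeded synthetic chromatogram generator.
#
# Emulates multi-peak HPLC-FD traces: Gaussian (or exponentially modified
# Gaussian, for tailing) peaks on a low-order polynomial baseline plus white
# detector noise. Peak positions are stated on the sample's own ("observed")
# time axis; an optional degree <= 2 warp records where each peak would sit
# on a reference axis, which is what retention-time calibration must
# recover.

#' Specify a synthetic peak
#'
#' @param center Peak position (minutes) on the simulated time axis.
#' @param sigma Gaussian width (minutes), > 0.
#' @param amplitude Apex height (signal units), > 0.
#' @param tau Exponential tail constant (minutes); 0 gives a pure Gaussian.
#' @return A one-row data.frame.
#' @export
peak_spec <- function(center, sigma, amplitude, tau = 0) {
  stopifnot(all(sigma > 0), all(amplitude > 0), all(tau >= 0))
  n <- length(center)
  data.frame(center = center, sigma = rep_len(sigma, n),
             amplitude = rep_len(amplitude, n), tau = rep_len(tau, n))
}

#' Specify a synthetic chromatogram
#'
#' @param peaks A data.frame of [peak_spec()] rows (may be rbind-ed).
#' @param t_start,t_end Time range (minutes), `t_start < t_end`.
#' @param tm Sampling interval (minutes), > 0.
#' @param baseline Ascending-degree polynomial coefficients of the drift
#'   baseline (default `c(0, 0)`).
#' @param noise_sd Standard deviation of additive white noise.
#' @param warp Ascending-degree coefficients (length <= 3) of the map from
#'   the simulated (observed) axis to the reference axis; default identity.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(peaks, t_start, t_end, tm = 0.01, baseline = c(0, 0),
                     noise_sd = 0, warp = c(0, 1), seed = 1L) {
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  if (tm <= 0) stop("sampling interval must be > 0", call. = FALSE)
  if (length(warp) > 3L) stop("warp degree must be <= 2", call. = FALSE)
  structure(list(peaks = peaks, t_start = t_start, t_end = t_end, tm = tm,
                 baseline = baseline, noise_sd = noise_sd, warp = warp,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a chromatogram with known ground truth
#'
#' The intensity is the sum of the peak shapes plus the baseline polynomial
#' plus N(0, `noise_sd`) noise; the same seed always yields the same trace.
#'
#' @param spec A [sim_spec()].
#' @param sample_id Sample identifier for the generated chromatogram.
#' @return A [chromatogram()] with attribute `ground_truth`: a data.frame
#'   with the true `center`, `sigma`, `amplitude`, `tau`, analytic `area`
#'   (`amplitude * sigma * sqrt(2*pi)`, preserved under tailing) and
#'   `center_ref`, the peak position mapped onto the reference axis by the
#'   warp.
#' @export
simulate_chromatogram <- function(spec, sample_id = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  t <- seq(spec$t_start, spec$t_end, by = spec$tm)
  y <- polyval(spec$baseline, t)
  pk <- spec$peaks
  if (!is.null(pk) && nrow(pk) > 0L) {
    for (i in seq_len(nrow(pk))) {
      y <- y + emg_shape(t, pk$amplitude[i], pk$center[i], pk$sigma[i],
                         pk$tau[i])
    }
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(spec$seed)
    y <- y + stats::rnorm(length(t), sd = spec$noise_sd)
    .Random.seed_restore(old)
  }
  ch <- chromatogram(t, y, sample_id = sample_id, dialect = NA_character_)
  gt <- if (!is.null(pk) && nrow(pk) > 0L) {
    data.frame(center = pk$center, sigma = pk$sigma,
               amplitude = pk$amplitude, tau = pk$tau,
               area = gauss_area(pk$amplitude, pk$sigma),
               center_ref = polyval(spec$warp, pk$center))
  } else {
    data.frame(center = numeric(), sigma = numeric(), amplitude = numeric(),
               tau = numeric(), area = numeric(), center_ref = numeric())
  }
  attr(ch, "ground_truth") <- gt
  ch
}

# save/restore global RNG state so simulation seeds do not leak
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic per-replicate seed derived from the master seed; kept well
# below 2^31
replicate_seed <- function(seed, i) {
  (as.integer(seed) %% 100000L) * 10000L + 7919L * (as.integer(i) %% 1000L)
}

#' Simulate replicate injections
#'
#' Generates `n` replicates of the profile in `spec`: per replicate the
#' amplitudes are jittered lognormally with coefficient of variation
#' `area_cv` and the centers are jittered normally with standard deviation
#' `shift_sd`. Replicate seeds derive deterministically from the master
#' seed.
#'
#' @param spec A [sim_spec()].
#' @param n Number of replicates, >= 1.
#' @param area_cv Fractional CV of injected amplitudes (0.01 = 1 percent).
#' @param shift_sd Standard deviation of retention-time jitter (minutes).
#' @return A list of `n` chromatograms, each with its own `ground_truth`
#'   attribute; sample ids are `rep1..repN`.
#' @export
simulate_replicates <- function(spec, n, area_cv = 0, shift_sd = 0) {
  stopifnot(inherits(spec, "sim_spec"), n >= 1L)
  sdlog <- sqrt(log(1 + area_cv^2))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- replicate_seed(spec$seed, i)
    pk <- spec$peaks
    if (nrow(pk) > 0L && (area_cv > 0 || shift_sd > 0)) {
      old <- .Random.seed_save()
      set.seed(replicate_seed(spec$seed, i) + 1L)
      if (area_cv > 0) {
        pk$amplitude <- pk$amplitude *
          stats::rlnorm(nrow(pk), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      if (shift_sd > 0) {
        pk$center <- pk$center + stats::rnorm(nrow(pk), sd = shift_sd)
      }
      .Random.seed_restore(old)
      si$peaks <- pk
    }
    out[[i]] <- simulate_chromatogram(si, sample_id = sprintf("rep%d", i))
  }
  out
}
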