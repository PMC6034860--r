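# Processing configuration.

#' Processing configuration
#'
#' Bundles the tunable parameters of the processing pipeline. Defaults match
#' a typical HILIC glycopeptide run: detection/quantitation region 11-25
#' min, 1.0 min background window, degree-1 baseline over 100-point blocks,
#' 4 calibrants at S/N >= 9, 1 percent detection cutoff, +/- 0.15 min
#' default quantitation half-window.
#'
#' @param start_tr,end_tr Processing region bounds (minutes).
#' @param background_window Half-width (minutes) of the region searched for
#'   an analyte's local background.
#' @param baseline_order Baseline polynomial degree (0-2).
#' @param baseline_points Data points per baseline/noise block.
#' @param min_calibrants Minimum retained calibrants (>= 3).
#' @param min_sn Minimum calibrant signal-to-noise.
#' @param cutoff_fraction Peak-detection intensity cutoff (fraction of the
#'   initial maximum).
#' @param quant_window Default analyte half-window (minutes).
#' @param max_iterations Detection iteration cap.
#' @param spline_smoothing Detection spline smoothing (`NULL` = automatic).
#' @param subtract_background Subtract the local background during
#'   integration.
#' @return A list of class `processing_config`.
#' @export
processing_config <- function(start_tr = 11, end_tr = 25,
                              background_window = 1.0, baseline_order = 1L,
                              baseline_points = 100L, min_calibrants = 4L,
                              min_sn = 9, cutoff_fraction = 0.01,
                              quant_window = 0.15, max_iterations = 50L,
                              spline_smoothing = NULL,
                              subtract_background = TRUE) {
  if (!(start_tr < end_tr)) stop("start_tr must be < end_tr", call. = FALSE)
  for (v in c(background_window, baseline_points, min_calibrants, min_sn,
              cutoff_fraction, quant_window, max_iterations)) {
    if (!is.finite(v) || v <= 0) {
      stop("all thresholds must be positive", call. = FALSE)
    }
  }
  structure(list(start_tr = start_tr, end_tr = end_tr,
                 background_window = background_window,
                 baseline_order = as.integer(baseline_order),
                 baseline_points = as.integer(baseline_points),
                 min_calibrants = as.integer(min_calibrants),
                 min_sn = min_sn, cutoff_fraction = cutoff_fraction,
                 quant_window = quant_window,
                 max_iterations = as.integer(max_iterations),
                 spline_smoothing = spline_smoothing,
                 subtract_background = isTRUE(subtract_background)),
            class = "processing_config")
}

#' Read a configuration file
#'
#' Parses a plain `key = value` file (one pair per line, `#` comments
#' allowed) whose keys mirror the [processing_config()] arguments, and
#' merges it over the defaults. Unknown keys raise an error.
#'
#' @param path Path to the config file.
#' @return A [processing_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop(sprintf("%s: malformed line '%s'", basename(path), ln),
           call. = FALSE)
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(processing_config))) {
      stop(sprintf("%s: unknown config key '%s'", basename(path), key),
           call. = FALSE)
    }
    args[[key]] <- if (val %in% c("true", "TRUE", "false", "FALSE")) {
      toupper(val) == "TRUE"
    } else if (val %in% c("NULL", "null")) {
      NULL
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) stop(sprintf("%s: non-numeric value for '%s'",
                                 basename(path), key), call. = FALSE)
      v
    }
  }
  do.call(processing_config, args)
}
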