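## Kinematics: from raw accelerometer frames to a drift-angle time series.
##
## The drift test is quasi-static: the limb is held against gravity for 20 s,
## so the accelerometer reading is dominated by the gravity direction in the
## sensor frame. The limb-axis elevation (pitch above horizontal) is then
## asin of the longitudinal gravity component, and drift is the signed change
## in elevation relative to a calibration window at the start of the test.

LIMB_IDS <- c("ULL", "URL", "LLL", "LRL")

#' Construct a limb accelerometer recording
#'
#' @param t numeric vector, seconds from test start, strictly increasing.
#' @param ax,ay,az acceleration in g along the sensor axes; `x` is the limb
#'   longitudinal axis by the default mounting convention.
#' @param limb_id one of `"ULL"`, `"URL"`, `"LLL"`, `"LRL"` (upper/lower,
#'   left/right limb).
#' @param sample_rate_hz nominal sampling frequency; inferred from the median
#'   time step when `NULL`.
#' @param subject_id opaque subject identifier.
#' @return object of class `limb_recording`: a data frame with columns
#'   `t, ax, ay, az` and attributes `limb_id`, `subject_id`, `sample_rate_hz`.
#' @export
limb_recording <- function(t, ax, ay, az, limb_id = "ULL",
                           sample_rate_hz = NULL, subject_id = "anon") {
  if (length(t) < 2L)
    stop_dg("a recording needs at least 2 samples", class = "dg_invalid_input")
  if (length(ax) != length(t) || length(ay) != length(t) ||
      length(az) != length(t))
    stop_dg("t, ax, ay, az must have equal length", class = "dg_invalid_input")
  if (!all(is.finite(t)) || any(t < 0))
    stop_dg("t must be finite and non-negative", class = "dg_invalid_input")
  if (any(diff(t) <= 0))
    stop_dg("t must be strictly increasing", class = "dg_invalid_input")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop_dg("acceleration values must be finite", class = "dg_invalid_input")
  limb_id <- match.arg(limb_id, LIMB_IDS)
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / stats::median(diff(t))
  mag <- sqrt(ax^2 + ay^2 + az^2)
  n_off <- sum(mag < 0.5 | mag > 1.5)
  if (n_off > 0L)
    message(sprintf(
      "limb_recording: %d/%d frames outside [0.5, 1.5] g (dynamic motion?)",
      n_off, length(t)))
  structure(data.frame(t = t, ax = ax, ay = ay, az = az),
            limb_id = limb_id, subject_id = subject_id,
            sample_rate_hz = sample_rate_hz,
            class = c("limb_recording", "data.frame"))
}

#' @export
print.limb_recording <- function(x, ...) {
  cat(sprintf("<limb_recording> %s/%s: %d samples, %.1f s @ %.1f Hz\n",
              attr(x, "subject_id"), attr(x, "limb_id"), nrow(x),
              x$t[nrow(x)] - x$t[1L], attr(x, "sample_rate_hz")))
  invisible(x)
}

## centered moving average with shrinking windows at the edges
moving_average <- function(x, n) {
  if (n <= 1L) return(x)
  N <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(N) - floor((n - 1L) / 2L))
  hi <- pmin(N, seq_len(N) + ceiling((n - 1L) / 2L))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing of a recording
#'
#' Applies a centered moving average of `round(window_s * sample_rate_hz)`
#' samples to each axis; edge frames average over the neighbors available.
#' `window_s = 0` returns the input unchanged.
#'
#' @param recording a [limb_recording()].
#' @param window_s smoothing window in seconds (default 0.5).
#' @return smoothed `limb_recording` on the same time base.
#' @export
smooth_recording <- function(recording, window_s = 0.5) {
  if (!inherits(recording, "limb_recording") || nrow(recording) == 0L)
    stop_dg("recording must be a non-empty limb_recording",
            class = "dg_invalid_input")
  if (window_s < 0)
    stop_dg("window_s must be >= 0", class = "dg_invalid_input")
  if (window_s == 0) return(recording)
  n <- round(window_s * attr(recording, "sample_rate_hz"))
  if (n <= 1L) return(recording)
  out <- recording
  for (ax in c("ax", "ay", "az")) out[[ax]] <- moving_average(recording[[ax]], n)
  out
}

#' Estimate the zero-drift reference orientation
#'
#' Averages the accelerometer vector over a calibration window at the start
#' of the hold and normalizes it; the result is the gravity direction in the
#' sensor frame for the calibrated pose and defines drift angle zero.
#'
#' @param recording a [limb_recording()].
#' @param calib_window numeric `c(t0, t1)` in seconds (default `c(0, 2)`).
#' @return object of class `orientation` with field `gravity_dir`
#'   (unit 3-vector).
#' @export
estimate_reference_orientation <- function(recording, calib_window = c(0, 2)) {
  sel <- recording$t >= calib_window[1L] & recording$t <= calib_window[2L]
  if (!any(sel))
    stop_dg("no samples in calibration window [%g, %g]",
            calib_window[1L], calib_window[2L], class = "dg_invalid_input")
  g <- c(mean(recording$ax[sel]), mean(recording$ay[sel]),
         mean(recording$az[sel]))
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-12)
    stop_dg("degenerate calibration: mean acceleration has zero norm",
            class = "dg_degenerate_calibration")
  structure(list(gravity_dir = g / nrm), class = "orientation")
}

elevation_deg <- function(g_long) asin(pmin(1, pmax(-1, g_long))) * 180 / pi

#' Compute the drift-angle time series
#'
#' For each (smoothed) frame the normalized accelerometer vector estimates
#' the gravity direction; the limb-axis elevation is
#' `asin(g_longitudinal) * 180 / pi` degrees (pitch of the limb axis above
#' horizontal, up to sign of the mounting), and the drift angle is the
#' elevation minus the elevation of the calibration reference. Positive
#' drift means the limb is above the calibrated pose; downward drift is
#' negative.
#'
#' @param recording a [limb_recording()].
#' @param reference an `orientation` from [estimate_reference_orientation()];
#'   computed from the default calibration window when `NULL`.
#' @param smoothing_s moving-average window in seconds applied before angle
#'   estimation (default 0.5; 0 disables smoothing).
#' @param longitudinal_axis which sensor axis lies along the limb
#'   (`"ax"`, `"ay"` or `"az"`; default `"ax"`).
#' @return object of class `drift_series`: data frame with columns `t`
#'   (seconds) and `theta_drift` (signed degrees), attribute `limb_id`.
#'   Frames with zero-norm acceleration are dropped with a warning; more
#'   than 10\% dropped is an error.
#' @export
compute_drift_series <- function(recording, reference = NULL,
                                 smoothing_s = 0.5,
                                 longitudinal_axis = c("ax", "ay", "az")) {
  longitudinal_axis <- match.arg(longitudinal_axis)
  sm <- smooth_recording(recording, smoothing_s)
  if (is.null(reference)) reference <- estimate_reference_orientation(sm)
  if (!inherits(reference, "orientation"))
    stop_dg("reference must be an orientation", class = "dg_invalid_input")
  g <- as.matrix(sm[, c("ax", "ay", "az")])
  nrm <- sqrt(rowSums(g^2))
  keep <- nrm > 1e-12
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warn_dg("%d frame(s) with zero-norm acceleration skipped", n_drop,
            class = "dg_frames_skipped")
    if (n_drop > 0.1 * nrow(sm))
      stop_dg("more than 10%% of frames unusable (%d/%d)", n_drop, nrow(sm),
              class = "dg_invalid_recording")
  }
  ax_idx <- match(longitudinal_axis, c("ax", "ay", "az"))
  elev <- elevation_deg(g[keep, ax_idx] / nrm[keep])
  elev_ref <- elevation_deg(reference$gravity_dir[ax_idx])
  structure(data.frame(t = sm$t[keep], theta_drift = elev - elev_ref),
            limb_id = attr(recording, "limb_id"),
            class = c("drift_series", "data.frame"))
}

#' @export
print.drift_series <- function(x, ...) {
  cat(sprintf("<drift_series> %s: %d frames, theta in [%.1f, %.1f] deg\n",
              attr(x, "limb_id") %||% "?", nrow(x),
              min(x$theta_drift), max(x$theta_drift)))
  invisible(x)
}

#' Read / write recording and drift-series CSV files
#'
#' Recording files use the strict header `t,ax,ay,az` (seconds, g units) and
#' are named `<subject>_<limb>.csv`; drift series use `t,theta_drift_deg`.
#'
#' @param path CSV file path.
#' @param limb_id,subject_id,sample_rate_hz metadata for the recording;
#'   limb and subject are parsed from the filename when `NULL`.
#' @return [read_recording()] returns a `limb_recording`;
#'   [write_drift_series()] writes and returns `path` invisibly.
#' @export
read_recording <- function(path, limb_id = NULL, subject_id = NULL,
                           sample_rate_hz = NULL) {
  d <- utils::read.csv(path, colClasses = "numeric")
  missing_cols <- setdiff(c("t", "ax", "ay", "az"), names(d))
  if (length(missing_cols))
    stop_dg("recording CSV missing column(s): %s",
            paste(missing_cols, collapse = ", "), class = "dg_schema_error")
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (is.null(limb_id) && length(parts) >= 2L &&
      parts[length(parts)] %in% LIMB_IDS) {
    limb_id <- parts[length(parts)]
    subject_id <- subject_id %||% paste(parts[-length(parts)], collapse = "_")
  }
  limb_recording(d$t, d$ax, d$ay, d$az, limb_id = limb_id %||% "ULL",
                 sample_rate_hz = sample_rate_hz,
                 subject_id = subject_id %||% "anon")
}

#' @rdname read_recording
#' @param recording a `limb_recording` to write.
#' @export
write_recording <- function(recording, path) {
  utils::write.csv(as.data.frame(recording)[, c("t", "ax", "ay", "az")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_recording
#' @param series a `drift_series` to write.
#' @export
write_drift_series <- function(series, path) {
  utils::write.csv(data.frame(t = series$t, theta_drift_deg = series$theta_drift),
                   path, row.names = FALSE)
  invisible(path)
}
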