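# Preprocessing: unit conversion, gap-aware resampling to 32 Hz, windowing.

#' Convert a recording to m/s^2
#'
#' g/64 counts and g readings are converted with standard gravity
#' (9.80665 m/s^2); m/s^2 input is returned unchanged.
#'
#' @param recording a [sensor_recording].
#' @return The recording with `acc` in m/s^2 and the unit tag updated.
#' @export
convert_units <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"))
  acc <- switch(recording$unit,
                m_s2 = recording$acc,
                g = recording$acc * STANDARD_GRAVITY,
                g64 = recording$acc / 64 * STANDARD_GRAVITY,
                stop("unknown unit tag: ", recording$unit, call. = FALSE))
  recording$acc <- acc
  recording$unit <- "m_s2"
  recording
}

#' Resample a recording onto a uniform grid with a gap rule
#'
#' Linear interpolation onto an exact `1/rate` grid spanning the recording.
#' A grid point whose bracketing raw samples are more than `max_gap` seconds
#' apart is marked invalid instead of being interpolated, so that long
#' dropouts never manufacture synthetic data; invalid spans are excluded from
#' windowing downstream.
#'
#' @param recording a [sensor_recording] with >= 2 samples.
#' @param rate target uniform rate in Hz (default 32).
#' @param max_gap largest raw inter-sample gap, in seconds, across which
#'   interpolation is still trusted (default 1 s).
#' @return A [sensor_recording] on the uniform grid with a `valid` mask.
#' @export
regularize_sampling <- function(recording, rate = 32, max_gap = 1) {
  stopifnot(inherits(recording, "sensor_recording"), rate > 0, max_gap > 0)
  ts <- recording$timestamps
  if (length(ts) < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  t0 <- ts[1]
  grid <- t0 + seq(0, floor((ts[length(ts)] - t0) * rate + 1e-9)) / rate
  X <- vapply(1:3, function(j) {
    stats::approx(ts, recording$acc[, j], xout = grid)$y
  }, numeric(length(grid)))
  # A grid point is invalid when the raw gap bracketing it exceeds max_gap.
  left <- findInterval(grid + 1e-12, ts)
  left <- pmin(pmax(left, 1L), length(ts) - 1L)
  gap <- ts[left + 1L] - ts[left]
  on_node <- abs(grid - ts[left]) < 1e-9 | abs(grid - ts[left + 1L]) < 1e-9
  valid <- on_node | gap <= max_gap + 1e-12
  sensor_recording(recording$sensor_id, grid, X, unit = recording$unit,
                   valid = valid)
}

#' Segment a uniform recording into single-task windows
#'
#' Non-overlapping windows of `window_s` seconds tile each annotated interval
#' from its start.  A window is emitted only if it lies entirely inside one
#' annotated interval and contains no invalid (non-interpolated) samples;
#' trailing partial windows are dropped.  At 32 Hz a 10 s window holds 320
#' samples and a 4 s window 128.
#'
#' @param recording a uniform [sensor_recording] (output of
#'   [regularize_sampling]) in m/s^2.
#' @param annotations an [annotation_track].
#' @param window_s window length in seconds; `window_s * rate` must be an
#'   integer.
#' @param rate sampling rate in Hz (default 32).
#' @param meta metadata list copied onto every emitted window.
#' @return A list of `labelled_window` objects, each with fields `label`,
#'   `samples` (`window_s * rate` x 3 matrix), `start_s` and `meta`.
#' @export
segment_windows <- function(recording, annotations, window_s = 10, rate = 32,
                            meta = list()) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(annotations, "annotation_track"))
  wlen <- window_s * rate
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("`window_s * rate` must be an integer sample count", call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  ts <- recording$timestamps
  if (length(ts) > 1L) {
    dts <- diff(ts)
    if (max(abs(dts - 1 / rate)) > 1e-6) {
      stop("recording is not uniform at the requested rate; ",
           "run regularize_sampling() first", call. = FALSE)
    }
  }
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    a0 <- annotations$start_s[i]
    a1 <- annotations$end_s[i]
    idx <- which(ts >= a0 - 1e-9 & ts < a1 - 1e-9)
    if (length(idx) < wlen) next
    n_win <- length(idx) %/% wlen
    for (w in seq_len(n_win)) {
      sel <- idx[((w - 1L) * wlen + 1L):(w * wlen)]
      if (!all(recording$valid[sel])) next
      out[[length(out) + 1L]] <- structure(
        list(label = annotations$label[i],
             samples = recording$acc[sel, , drop = FALSE],
             start_s = ts[sel[1]],
             meta = c(meta, list(sensor_id = recording$sensor_id))),
        class = "labelled_window")
    }
  }
  out
}
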