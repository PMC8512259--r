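# Synthetic cohort / session generator.
#
# The generator does not attempt biomechanical realism: each occupational task
# is a surrogate signature (a gravity component along a task-specific wrist
# orientation plus a quasi-periodic component with a task-specific fundamental
# frequency and amplitude).  What matters downstream is that task signatures
# are distinct and that subject- and sensor-level perturbations induce the
# kinds of distribution shift seen between real devices and wearers.

#' Occupational task vocabulary
#'
#' Ten wrist-accelerometer task labels: electrical panel work (EP), hoisting
#' (H), ladder climbing (Ld), lifting (Lf), overhead work (OH), pushing a cart
#' (P), sitting (St), standing (Sd), typing (Tp) and walking (W).
#' @export
TASKS <- c("EP", "H", "Ld", "Lf", "OH", "P", "St", "Sd", "Tp", "W")

# Per-task surrogate parameters: wrist orientation (unit vector the gravity
# vector points along in the device frame), fundamental frequency (Hz) and
# oscillation amplitude (m/s^2).  Static postures have zero amplitude.
task_table <- function() {
  tab <- list(
    EP = list(orient = c(0.20, 0.90, 0.40), freq = 2.4, amp = 1.2),
    H  = list(orient = c(0.90, 0.10, 0.40), freq = 0.5, amp = 3.0),
    Ld = list(orient = c(0.50, 0.70, 0.50), freq = 1.2, amp = 2.5),
    Lf = list(orient = c(0.70, 0.50, 0.50), freq = 0.4, amp = 2.8),
    OH = list(orient = c(0.10, 0.30, 0.95), freq = 1.7, amp = 1.5),
    P  = list(orient = c(0.80, 0.40, 0.45), freq = 0.9, amp = 2.0),
    St = list(orient = c(0.30, 0.10, 0.95), freq = 0.0, amp = 0.0),
    Sd = list(orient = c(0.95, 0.20, 0.25), freq = 0.0, amp = 0.0),
    Tp = list(orient = c(0.25, 0.20, 0.95), freq = 3.2, amp = 0.8),
    W  = list(orient = c(0.90, 0.30, 0.30), freq = 2.0, amp = 2.2)
  )
  lapply(tab, function(p) {
    p$orient <- p$orient / sqrt(sum(p$orient^2))
    p
  })
}

#' Subject profile constructor
#'
#' A subject is modelled by a per-axis gain, a wrist-orientation rotation, a
#' tempo multiplier on task fundamental frequencies, and a sensor-frame noise
#' level.
#'
#' @param subject_id character identifier.
#' @param gain positive length-3 per-axis scale (unitless).
#' @param rotation 3x3 rotation matrix (determinant +1).
#' @param tempo positive scalar multiplier on task frequencies.
#' @param noise_sd nonnegative noise standard deviation in m/s^2
#'   (default 1, a busy-wrist movement floor).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gain = c(1, 1, 1), rotation = diag(3),
                            tempo = 1, noise_sd = 1) {
  gain <- as.numeric(gain)
  if (length(gain) == 1L) gain <- rep(gain, 3L)
  if (length(gain) != 3L || any(!is.finite(gain)) || any(gain <= 0)) {
    stop("`gain` must be three positive finite values", call. = FALSE)
  }
  if (!is_rotation(rotation)) {
    stop("`rotation` must be a 3x3 rotation matrix (orthogonal, det +1)",
         call. = FALSE)
  }
  if (!is.numeric(tempo) || tempo <= 0) stop("`tempo` must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), gain = gain,
                 rotation = rotation, tempo = tempo, noise_sd = noise_sd),
            class = "subject_profile")
}

#' Generate a cohort of subject profiles
#'
#' Profile parameters are drawn from ranges whose spread scales with
#' `heterogeneity_level`; level 0 yields identical idealized subjects (unit
#' gain, identity rotation, tempo 1).  `heterogeneity_level` may be a vector
#' (recycled over subjects) so that a single subject can be made an outlier.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param heterogeneity_level nonnegative scalar or per-subject vector.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param noise_sd baseline sensor-frame noise level, m/s^2.
#' @return A list of [subject_profile] objects.
#' @export
make_cohort <- function(n_subjects, heterogeneity_level = 1, seed = 1,
                        noise_sd = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 0 ||
      n_subjects != round(n_subjects)) {
    stop("`n_subjects` must be a nonnegative integer", call. = FALSE)
  }
  if (any(heterogeneity_level < 0)) {
    stop("`heterogeneity_level` must be nonnegative", call. = FALSE)
  }
  if (n_subjects == 0L) return(list())
  lev <- rep_len(as.numeric(heterogeneity_level), n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    h <- lev[i]
    with_seed(subseed(seed, 11L, i), {
      gain <- exp(stats::rnorm(3, 0, 0.08 * h))
      axis <- stats::rnorm(3)
      angle <- stats::rnorm(1, 0, 0.25 * h)
      rot <- if (h == 0) diag(3) else rotation_about_axis(axis, angle)
      tempo <- exp(stats::rnorm(1, 0, 0.08 * h))
      nsd <- noise_sd * exp(stats::rnorm(1, 0, 0.2 * h))
      subject_profile(sprintf("S%02d", i), gain = gain, rotation = rot,
                      tempo = tempo, noise_sd = nsd)
    })
  })
}

#' Sensor model constructor
#'
#' Describes how a wrist device observes ideal motion: its native measurement
#' unit, its (possibly jittered) sampling clock, per-axis miscalibration, an
#' axis-convention/mounting rotation relative to the reference frame, and a
#' dropout process deleting short spans of samples.
#'
#' @param sensor_id character identifier.
#' @param unit one of `"g64"` (1 g reads as 64), `"g"`, `"m_s2"`.
#' @param rate_hz mean sampling rate in Hz.
#' @param jitter_sd standard deviation of inter-sample interval jitter in
#'   seconds; 0 means a perfectly uniform clock.
#' @param bias per-axis additive offset in the sensor's *native* unit.
#' @param scale_error per-axis multiplicative calibration error (unitless).
#' @param misalignment 3x3 rotation mapping reference-frame axes to device
#'   axes (mounting / axis-convention difference between devices).
#' @param dropout_rate_per_min expected dropout events per minute.
#' @param dropout_duration_s length-2 range (seconds) of uniform dropout
#'   durations; both entries must be > 0 when dropouts occur.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(sensor_id, unit = c("m_s2", "g", "g64"),
                         rate_hz = 32, jitter_sd = 0,
                         bias = c(0, 0, 0), scale_error = c(1, 1, 1),
                         misalignment = diag(3),
                         dropout_rate_per_min = 0,
                         dropout_duration_s = c(0.5, 1.5)) {
  unit <- match.arg(unit)
  stopifnot(rate_hz > 0, jitter_sd >= 0, length(bias) == 3,
            length(scale_error) == 3, dropout_rate_per_min >= 0,
            length(dropout_duration_s) == 2)
  if (!is_rotation(misalignment)) {
    stop("`misalignment` must be a 3x3 rotation matrix", call. = FALSE)
  }
  if (dropout_rate_per_min > 0 && any(dropout_duration_s <= 0)) {
    stop("dropout durations must be > 0", call. = FALSE)
  }
  structure(list(sensor_id = as.character(sensor_id), unit = unit,
                 rate_hz = rate_hz, jitter_sd = jitter_sd,
                 bias = as.numeric(bias), scale_error = as.numeric(scale_error),
                 misalignment = misalignment,
                 dropout_rate_per_min = dropout_rate_per_min,
                 dropout_duration_s = sort(as.numeric(dropout_duration_s))),
            class = "sensor_model")
}

#' Default wrist devices
#'
#' `sensor_uniform_g64()` is a well-behaved research wristband: uniform 32 Hz
#' clock, native unit g/64, no miscalibration.  `sensor_uneven_g()` is a
#' consumer-grade counterpart: uneven sampling around 20 Hz, native unit g,
#' per-axis bias and gain error, a rotated axis convention and occasional
#' Bluetooth dropouts (some longer than 1 s, so the gap rule is exercised).
#' @rdname default_sensors
#' @export
sensor_uniform_g64 <- function() {
  sensor_model("sensor1", unit = "g64", rate_hz = 32, jitter_sd = 0)
}

#' @rdname default_sensors
#' @export
sensor_uneven_g <- function() {
  sensor_model("sensor2", unit = "g", rate_hz = 20, jitter_sd = 0.015,
               bias = c(0.05, -0.04, 0.06), scale_error = c(1.10, 0.90, 1.05),
               misalignment = rotation_about_axis(c(0.4, 0.7, 0.6), 1.2),
               dropout_rate_per_min = 0.5, dropout_duration_s = c(0.2, 2.5))
}

#' Scenario specifications
#'
#' `scenario_separate()` runs each task as exactly one contiguous block (the
#' conventional lab protocol).  `scenario_mixed()` interleaves single short
#' bouts of each task in `circuits` randomized circuits over `total_s`
#' seconds (the realistic dispersed protocol); typing is not allowed there.
#'
#' @param tasks task label subset of [TASKS].
#' @param block_s separate-scenario block length per task, seconds.
#' @param circuits number of circuit repetitions (mixed only).
#' @param total_s total mixed-session duration, seconds.
#' @return An object of class `scenario_spec`.
#' @rdname scenarios
#' @export
scenario_separate <- function(tasks = TASKS, block_s = 60) {
  stopifnot(length(tasks) >= 1, block_s > 0)
  if (!all(tasks %in% TASKS)) stop("unknown task label", call. = FALSE)
  if (anyDuplicated(tasks)) stop("duplicated task label", call. = FALSE)
  structure(list(kind = "separate", tasks = tasks, block_s = block_s,
                 total_s = block_s * length(tasks)),
            class = "scenario_spec")
}

#' @rdname scenarios
#' @export
scenario_mixed <- function(tasks = setdiff(TASKS, "Tp"), circuits = 7,
                           total_s = 3600) {
  stopifnot(length(tasks) >= 1, circuits >= 1, total_s > 0)
  if (!all(tasks %in% TASKS)) stop("unknown task label", call. = FALSE)
  if ("Tp" %in% tasks) {
    stop("typing (Tp) is not performed in the mixed scenario", call. = FALSE)
  }
  structure(list(kind = "mixed", tasks = tasks, circuits = as.integer(circuits),
                 total_s = total_s),
            class = "scenario_spec")
}

#' Sensor recording constructor
#'
#' @param sensor_id character identifier.
#' @param timestamps strictly increasing times in seconds.
#' @param acc n x 3 acceleration matrix in `unit`.
#' @param unit measurement unit tag.
#' @param valid optional logical validity mask (used by the resampler to mark
#'   grid points inside long gaps).
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(sensor_id, timestamps, acc,
                             unit = c("m_s2", "g", "g64"), valid = NULL) {
  unit <- match.arg(unit)
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("`acc` must have three columns", call. = FALSE)
  if (length(timestamps) != nrow(acc)) {
    stop("timestamp / sample length mismatch", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (anyNA(timestamps) || anyNA(acc)) stop("NA in recording", call. = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, length(timestamps))
  colnames(acc) <- c("ax", "ay", "az")
  structure(list(sensor_id = as.character(sensor_id),
                 timestamps = as.numeric(timestamps), acc = acc, unit = unit,
                 valid = valid),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  dur <- if (length(x$timestamps)) diff(range(x$timestamps)) else 0
  cat(sprintf("<sensor_recording> %s: %d samples, %.1f s, unit %s\n",
              x$sensor_id, length(x$timestamps), dur, x$unit))
  invisible(x)
}

#' Annotation track constructor
#'
#' @param label task labels (subset of [TASKS]).
#' @param start_s,end_s interval bounds in seconds; intervals must be pairwise
#'   non-overlapping with `start < end`.
#' @return A `data.frame` of class `annotation_track`.
#' @export
annotation_track <- function(label, start_s, end_s) {
  stopifnot(length(label) == length(start_s), length(start_s) == length(end_s))
  if (!all(label %in% TASKS)) stop("unknown task label", call. = FALSE)
  if (any(end_s <= start_s)) stop("intervals need start < end", call. = FALSE)
  ord <- order(start_s)
  df <- data.frame(label = as.character(label)[ord],
                   start_s = as.numeric(start_s)[ord],
                   end_s = as.numeric(end_s)[ord],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1L && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9)) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Ideal task waveform for one subject
#'
#' The template is a gravity component along the task's wrist orientation plus
#' a quasi-periodic component (fundamental + second harmonic along two
#' orthogonal directions) plus white noise.  The subject transform is
#' `rotation %*% (gain * template)` with frequencies scaled by `tempo`.
#'
#' @param task a label in [TASKS].
#' @param subject a [subject_profile].
#' @param t nonempty increasing time grid in seconds.
#' @param seed integer seed (phases, amplitude jitter and noise).
#' @return A `length(t)` x 3 matrix of ideal acceleration in m/s^2.
#' @export
task_waveform <- function(task, subject, t, seed = 1) {
  tab <- task_table()
  if (!task %in% names(tab)) stop("unknown task label: ", task, call. = FALSE)
  if (length(t) == 0 || (length(t) > 1 && any(diff(t) <= 0))) {
    stop("`t` must be nonempty and increasing", call. = FALSE)
  }
  p <- tab[[task]]
  o <- p$orient
  # Orthonormal pair spanning the plane normal to the wrist orientation.
  ref <- if (abs(o[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  d1 <- c(o[2] * ref[3] - o[3] * ref[2],
          o[3] * ref[1] - o[1] * ref[3],
          o[1] * ref[2] - o[2] * ref[1])
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- c(o[2] * d1[3] - o[3] * d1[2],
          o[3] * d1[1] - o[1] * d1[3],
          o[1] * d1[2] - o[2] * d1[1])
  n <- length(t)
  with_seed(subseed(seed, 29L, string_seed(task)), {
    template <- tcrossprod(rep(1, n), STANDARD_GRAVITY * o)
    if (p$amp > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      f <- p$freq * subject$tempo
      # Slow multiplicative envelope: effort varies within a session, so
      # window-level amplitude variation averages out over a block instead
      # of shifting a whole session.
      f_env <- stats::runif(1, 0.03, 0.08)
      env <- p$amp * (1 + 0.15 * sin(2 * pi * f_env * t + ph[3]))
      s1 <- env * sin(2 * pi * f * t + ph[1])
      s2 <- 0.4 * env * cos(2 * pi * 2 * f * t + ph[2])
      template <- template + tcrossprod(s1, d1) + tcrossprod(s2, d2)
    }
    if (subject$noise_sd > 0) {
      template <- template + matrix(stats::rnorm(3 * n, 0, subject$noise_sd), n, 3)
    }
    out <- sweep(template, 2, subject$gain, `*`) %*% t(subject$rotation)
    colnames(out) <- c("ax", "ay", "az")
    out
  })
}

#' Observe an ideal motion through a sensor model
#'
#' Resamples the ideal m/s^2 series onto the sensor's (possibly jittered)
#' timestamp grid by linear interpolation, applies the axis misalignment,
#' per-axis scale error and unit conversion, adds the native-unit bias, and
#' deletes dropout intervals.
#'
#' @param ideal a [sensor_recording] in m/s^2 on a uniform reference grid.
#' @param sensor a [sensor_model].
#' @param seed integer seed (clock jitter and dropout process).
#' @return A [sensor_recording] in the sensor's native unit.
#' @export
apply_sensor_model <- function(ideal, sensor, seed = 1) {
  stopifnot(inherits(ideal, "sensor_recording"), inherits(sensor, "sensor_model"))
  if (ideal$unit != "m_s2") stop("`ideal` must be in m/s^2", call. = FALSE)
  if (length(ideal$timestamps) == 0L) stop("empty ideal series", call. = FALSE)
  t0 <- ideal$timestamps[1]
  t1 <- ideal$timestamps[length(ideal$timestamps)]
  with_seed(subseed(seed, 37L, string_seed(sensor$sensor_id)), {
    if (sensor$jitter_sd == 0) {
      ts <- t0 + seq(0, floor((t1 - t0) * sensor$rate_hz)) / sensor$rate_hz
    } else {
      mean_dt <- 1 / sensor$rate_hz
      n_max <- ceiling((t1 - t0) / mean_dt * 1.5) + 8L
      dts <- pmax(mean_dt * 0.2, stats::rnorm(n_max, mean_dt, sensor$jitter_sd))
      ts <- t0 + cumsum(c(0, dts))
      ts <- ts[ts <= t1]
    }
    X <- vapply(1:3, function(j) {
      stats::approx(ideal$timestamps, ideal$acc[, j], xout = ts)$y
    }, numeric(length(ts)))
    X <- X %*% t(sensor$misalignment)
    X <- sweep(X, 2, sensor$scale_error, `*`)
    X <- switch(sensor$unit,
                m_s2 = X,
                g = X / STANDARD_GRAVITY,
                g64 = X / STANDARD_GRAVITY * 64)
    X <- sweep(X, 2, sensor$bias, `+`)
    keep <- rep(TRUE, length(ts))
    if (sensor$dropout_rate_per_min > 0) {
      n_ev <- stats::rpois(1, sensor$dropout_rate_per_min * (t1 - t0) / 60)
      if (n_ev > 0) {
        starts <- stats::runif(n_ev, t0, t1)
        durs <- stats::runif(n_ev, sensor$dropout_duration_s[1],
                             sensor$dropout_duration_s[2])
        for (k in seq_len(n_ev)) {
          keep[ts >= starts[k] & ts < starts[k] + durs[k]] <- FALSE
        }
      }
    }
    sensor_recording(sensor$sensor_id, ts[keep], X[keep, , drop = FALSE],
                     unit = sensor$unit)
  })
}

#' Simulate one annotated session
#'
#' Builds the scenario's annotation track (separate: one contiguous block per
#' task in randomized order; mixed: `circuits` randomized circuits of single
#' bouts), synthesizes the ideal motion on a uniform 32 Hz reference grid,
#' and observes it through the sensor model.  The ideal motion depends only
#' on (subject, scenario, seed), so two sensor models called with the same
#' seed observe the same underlying movement, as two devices worn on the same
#' wrist would.
#'
#' @param subject a [subject_profile].
#' @param sensor a [sensor_model].
#' @param scenario a `scenario_spec`.
#' @param seed integer seed.
#' @return A list with elements `recording` ([sensor_recording]) and
#'   `annotations` ([annotation_track]).
#' @export
simulate_session <- function(subject, sensor, scenario, seed = 1) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(sensor, "sensor_model"),
            inherits(scenario, "scenario_spec"))
  if (scenario$kind == "mixed" && "Tp" %in% scenario$tasks) {
    stop("typing (Tp) is not performed in the mixed scenario", call. = FALSE)
  }
  labels <- with_seed(subseed(seed, 41L), {
    if (scenario$kind == "separate") {
      sample(scenario$tasks)
    } else {
      unlist(lapply(seq_len(scenario$circuits),
                    function(i) sample(scenario$tasks)))
    }
  })
  bout_s <- if (scenario$kind == "separate") {
    scenario$block_s
  } else {
    scenario$total_s / length(labels)
  }
  starts <- (seq_along(labels) - 1) * bout_s
  ann <- annotation_track(labels, starts, starts + bout_s)
  total <- length(labels) * bout_s
  t <- seq(0, total - 1 / 32, by = 1 / 32)
  acc <- matrix(0, length(t), 3)
  for (i in seq_along(labels)) {
    idx <- which(t >= starts[i] - 1e-9 & t < starts[i] + bout_s - 1e-9)
    acc[idx, ] <- task_waveform(labels[i], subject, t[idx],
                                seed = subseed(seed, 43L, i))
  }
  ideal <- sensor_recording("ideal", t, acc, unit = "m_s2")
  rec <- apply_sensor_model(ideal, sensor, seed = subseed(seed, 47L))
  list(recording = rec, annotations = ann)
}
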