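test_that("make_cohort handles edge cases and is seeded", {
  expect_length(make_cohort(0, 1.0, seed = 7), 0)
  cohort0 <- make_cohort(5, 0.0, seed = 7)
  for (p in cohort0) {
    expect_equal(p$gain, c(1, 1, 1))
    expect_equal(p$rotation, diag(3))
    expect_equal(p$tempo, 1)
  }
  expect_identical(make_cohort(10, 1.0, seed = 7), make_cohort(10, 1.0, seed = 7))
  expect_false(identical(make_cohort(10, 1.0, seed = 7),
                         make_cohort(10, 1.0, seed = 8)))
  expect_error(make_cohort(-1, 1, 7), "nonnegative")
  expect_error(make_cohort(3, -0.5, 7), "nonnegative")
})

test_that("cohort profiles satisfy their invariants", {
  for (p in make_cohort(8, 2, seed = 3)) {
    expect_true(all(p$gain > 0))
    expect_lt(max(abs(crossprod(p$rotation) - diag(3))), 1e-10)
    expect_equal(det(p$rotation), 1, tolerance = 1e-10)
    expect_gt(p$tempo, 0)
    expect_gte(p$noise_sd, 0)
  }
})

test_that("static standing waveform averages to gravity", {
  subj <- subject_profile("A", noise_sd = 0.5)
  t <- seq(0, 20 - 1 / 32, 1 / 32)
  w <- task_waveform("Sd", subj, t, seed = 2)
  mean_vec <- colMeans(w)
  expect_lt(abs(sqrt(sum(mean_vec^2)) - 9.80665),
            3 * subj$noise_sd / sqrt(length(t)))
})

test_that("distinct tasks have distinct dominant frequencies (DFT oracle)", {
  subj <- subject_profile("A", noise_sd = 0)
  t <- seq(0, 16 - 1 / 32, 1 / 32)
  peak_freq <- function(task) {
    w <- task_waveform(task, subj, t, seed = 5)
    # project onto the axis with most oscillation energy
    sig <- w[, which.max(apply(w, 2, stats::var))]
    sig <- sig - mean(sig)
    n <- length(sig)
    p <- Mod(stats::fft(sig))^2
    ((0:(n - 1)) / n * 32)[which.max(p[2:(n %/% 2)]) + 1]
  }
  pw <- peak_freq("W")
  ph <- peak_freq("H")
  expect_equal(pw, 2.0, tolerance = 0.1)
  expect_equal(ph, 0.5, tolerance = 0.1)
  expect_gt(abs(pw - ph), 1)
})

test_that("task_waveform is seeded and rejects unknown labels", {
  subj <- subject_profile("A")
  t <- seq(0, 2, 1 / 32)
  expect_identical(task_waveform("W", subj, t, seed = 9),
                   task_waveform("W", subj, t, seed = 9))
  expect_error(task_waveform("XX", subj, t, 1), "unknown task")
  expect_error(task_waveform("W", subj, numeric(0), 1), "nonempty")
})

test_that("identity sensor model reproduces the ideal samplewise", {
  t <- seq(0, 5 - 1 / 32, 1 / 32)
  ideal <- sensor_recording("ideal", t, matrix(rnorm(length(t) * 3), ncol = 3),
                            unit = "m_s2")
  out <- apply_sensor_model(ideal, sensor_model("id", unit = "m_s2"), seed = 1)
  expect_equal(out$timestamps, ideal$timestamps)
  expect_equal(out$acc, ideal$acc, tolerance = 1e-12)
})

test_that("a g-unit sensor records standard gravity as 1.0", {
  t <- seq(0, 2, 1 / 32)
  ideal <- sensor_recording("ideal", t,
                            cbind(0 * t, 0 * t, rep(9.80665, length(t))),
                            unit = "m_s2")
  out <- apply_sensor_model(ideal, sensor_model("g", unit = "g"), seed = 1)
  expect_equal(unname(out$acc[, 3]), rep(1.0, length(out$timestamps)),
               tolerance = 1e-12)
})

test_that("a forced dropout leaves exactly one gap longer than its duration", {
  t <- seq(0, 60 - 1 / 32, 1 / 32)
  ideal <- sensor_recording("ideal", t, matrix(rnorm(length(t) * 3), ncol = 3),
                            unit = "m_s2")
  # one expected event per minute with a tight 2 s duration band
  sen <- sensor_model("drop", unit = "m_s2", dropout_rate_per_min = 1,
                      dropout_duration_s = c(2, 2.01))
  for (s in 1:20) {
    out <- apply_sensor_model(ideal, sen, seed = s)
    gaps <- diff(out$timestamps)
    expect_true(all(gaps > 0))
    n_long <- sum(gaps > 1.9)
    expect_true(all(gaps[gaps > 1.9] < 2.2))
    if (n_long == 1) break
  }
  expect_equal(n_long, 1)
  expect_error(apply_sensor_model(
    sensor_recording("e", numeric(0), matrix(numeric(), 0, 3), "m_s2"),
    sen, 1), "empty")
})

test_that("separate sessions have one contiguous block per task", {
  subj <- subject_profile("A")
  ses <- simulate_session(subj, sensor_uniform_g64(), scenario_separate(),
                          seed = 4)
  ann <- ses$annotations
  expect_equal(nrow(ann), 10)
  expect_setequal(ann$label, TASKS)
  expect_true(all(ann$start_s[-1] >= ann$end_s[-nrow(ann)] - 1e-9))
})

test_that("mixed sessions interleave circuits x tasks bouts without typing", {
  subj <- subject_profile("A")
  scn <- scenario_mixed(circuits = 7, total_s = 630)
  ses <- simulate_session(subj, sensor_uniform_g64(), scn, seed = 4)
  expect_equal(nrow(ses$annotations), 63)
  expect_false("Tp" %in% ses$annotations$label)
  expect_error(scenario_mixed(tasks = c("Tp", "W")), "Tp")
})

test_that("annotation intervals never overlap across many seeds", {
  subj <- subject_profile("A", noise_sd = 0)
  scn <- scenario_mixed(tasks = c("H", "W", "Sd"), circuits = 2, total_s = 60)
  for (s in 1:100) {
    ann <- simulate_session(subj, sensor_uniform_g64(), scn, seed = s)$annotations
    expect_true(all(ann$start_s[-1] >= ann$end_s[-nrow(ann)] - 1e-9))
    expect_true(all(ann$end_s > ann$start_s))
  }
})

test_that("sessions are byte-identical given the same seed", {
  subj <- make_cohort(1, 1, seed = 2)[[1]]
  scn <- scenario_separate(tasks = c("H", "W"), block_s = 20)
  s1 <- simulate_session(subj, sensor_uneven_g(), scn, seed = 11)
  s2 <- simulate_session(subj, sensor_uneven_g(), scn, seed = 11)
  expect_identical(s1, s2)
})

test_that("two sensors with one seed observe the same underlying motion", {
  subj <- subject_profile("A", noise_sd = 0.2)
  scn <- scenario_separate(tasks = c("Sd", "W"), block_s = 20)
  a <- simulate_session(subj, sensor_uniform_g64(), scn, seed = 6)
  b <- simulate_session(subj, sensor_model("other", unit = "m_s2"), scn,
                        seed = 6)
  # identity m/s^2 sensor returns the ideal; converting the g/64 recording
  # must recover the same motion on the shared grid
  conv <- convert_units(a$recording)
  expect_equal(conv$acc, b$recording$acc, tolerance = 1e-9)
  expect_identical(a$annotations, b$annotations)
})
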