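small_config <- function(k = 1, ...) {
  experiment_config(
    n_subjects = 3, k = k,
    scenario = scenario_separate(tasks = c("H", "W", "Sd"), block_s = 30),
    scenario_target = scenario_mixed(tasks = c("H", "W", "Sd"), circuits = 2,
                                     total_s = 240),
    ...)
}

test_that("cross-sensor runs produce one paired report per subject", {
  res <- run_cross_sensor(small_config(), seed = 51)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$summary), 3)
  expect_named(res$reports[[1]], c("da", "baseline"))
  expect_true(all(res$summary$acc_da >= 0 & res$summary$acc_da <= 1))
  expect_output(print(res), "cross-sensor")
})

test_that("experiment runs are reproducible from the master seed", {
  a <- run_cross_sensor(small_config(), seed = 52)
  b <- run_cross_sensor(small_config(), seed = 52)
  expect_identical(a$summary, b$summary)
  c1 <- run_cross_subject(small_config(), seed = 53)
  c2 <- run_cross_subject(small_config(), seed = 53)
  expect_identical(c1$summary, c2$summary)
})

test_that("k = n - 1 forces the DA and random selections to coincide", {
  cfg <- small_config(k = 2)
  res <- run_cross_subject(cfg, seed = 54)
  for (j in seq_along(res$reports)) {
    # every candidate is selected, so the ROD-ranked pool equals any
    # random draw's pool
    expect_setequal(res$reports[[j]]$selected, setdiff(1:3, j))
  }
})

test_that("ROD-ranked source pools are nested as k grows", {
  cfg <- experiment_config(
    n_subjects = 4, k = 1,
    scenario = scenario_separate(tasks = c("H", "W", "Sd"), block_s = 30))
  st <- gfkhar:::cross_subject_state(cfg, seed = 55)
  for (j in 1:4) {
    cand <- setdiff(1:4, j)
    ranked <- cand[order(st$rods[cand, j])]
    for (k in 1:2) {
      expect_true(all(ranked[seq_len(k)] %in% ranked[seq_len(k + 1)]))
    }
  }
})

test_that("joint experiment reduces to cross-subject with identical sensors", {
  cfg <- small_config(sensor_target = sensor_uniform_g64())
  a <- run_cross_subject(cfg, seed = 56)
  b <- run_joint(cfg, seed = 56)
  expect_equal(a$summary[, -1], b$summary[, -1], tolerance = 1e-12)
})

test_that("cross-scenario evaluates nine tasks and rejects typing targets", {
  cfg <- experiment_config(
    n_subjects = 2, k = 1,
    scenario = scenario_separate(block_s = 20),
    scenario_target = scenario_mixed(circuits = 2, total_s = 360),
    shared_scenario_cohort = TRUE)
  res <- run_cross_scenario(cfg, seed = 57)
  expect_equal(length(res$reports$pooled$da$per_task_f1), 9)
  expect_false("Tp" %in% names(res$reports$pooled$da$per_task_f1))
  bad <- cfg
  bad$scenario_target$tasks <- c(bad$scenario_target$tasks, "Tp")
  expect_error(run_cross_scenario(bad, seed = 57), "typing")
})

test_that("sensitivity_k reports both arms per k with a verifiable exclusion count", {
  cfg <- small_config()
  out <- sensitivity_k(cfg, k_range = 1:2, seed = 58)
  expect_equal(nrow(out), 4)
  expect_setequal(out$arm, c("da", "baseline"))
  expect_true(all(out$mean_accuracy >= 0 & out$mean_accuracy <= 1))
  expect_error(sensitivity_k(cfg, integer(0), 58), "empty")
  expect_error(sensitivity_k(cfg, 5, 58), "n_subjects")

  # recount oracle for the excluded-case numbers at k = 1
  st <- gfkhar:::cross_subject_state(cfg, seed = 58)
  vocab <- cfg$scenario$tasks
  recount <- c(da = 0L, baseline = 0L)
  for (j in 1:3) {
    cand <- setdiff(1:3, j)
    sel <- cand[order(st$rods[cand, j])][1]
    pick <- gfkhar:::with_seed(gfkhar:::subseed(58, 7L, j, 1L),
                               sample(cand, 1))
    tgt <- st$target_domains[[j]]
    pd <- fit_predict_da(gfkhar:::pool_domains(st$source_domains[sel]), tgt)
    pb <- fit_predict_baseline(gfkhar:::pool_domains(st$source_domains[pick]),
                               tgt)
    recount["da"] <- recount["da"] +
      sum(is.na(evaluate(tgt$labels, pd, vocab)$per_task_f1))
    recount["baseline"] <- recount["baseline"] +
      sum(is.na(evaluate(tgt$labels, pb, vocab)$per_task_f1))
  }
  expect_equal(out$excluded_cases[out$k == 1 & out$arm == "da"],
               unname(recount["da"]))
  expect_equal(out$excluded_cases[out$k == 1 & out$arm == "baseline"],
               unname(recount["baseline"]))
})

test_that("experiment_config validates its bounds", {
  expect_error(experiment_config(n_subjects = 3, k = 3), "k")
  expect_error(experiment_config(n_subjects = 1), "n_subjects")
})

test_that("an identity sensor pair leaves adaptation and baseline equivalent", {
  cfg <- small_config(sensor_target = sensor_uniform_g64())
  gaps <- vapply(1:5, function(s) {
    sm <- run_cross_sensor(cfg, seed = 70 + s)$summary
    mean(sm$acc_da - sm$acc_baseline)
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.02)
})

test_that("subject heterogeneity degrades both arms; adaptation never lags", {
  mkcfg <- function(h) experiment_config(
    n_subjects = 4, k = 2, heterogeneity = h,
    scenario = scenario_separate(block_s = 60))
  res <- vapply(1:10, function(s) {
    a0 <- run_cross_subject(mkcfg(0), seed = 600 + s)$summary
    a3 <- run_cross_subject(mkcfg(3), seed = 600 + s)$summary
    c(da0 = mean(a0$acc_da), ba0 = mean(a0$acc_baseline),
      da3 = mean(a3$acc_da), ba3 = mean(a3$acc_baseline))
  }, numeric(4))
  m <- rowMeans(res)
  # no-shift cohort: the two arms agree
  expect_lt(abs(m["da0"] - m["ba0"]), 0.02)
  # heterogeneity hurts both arms materially
  expect_gt(m["ba0"] - m["ba3"], 0.1)
  expect_gt(m["da0"] - m["da3"], 0.1)
  # and the adapted arm does not fall behind the baseline on average
  expect_gt(m["da3"] - m["ba3"], -0.02)
})
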