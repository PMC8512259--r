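# Orchestration of the four heterogeneity investigations (cross-sensor,
# cross-subject, joint, cross-scenario) and the k-sensitivity analysis,
# always as paired DA-vs-baseline comparisons on identical windows.

#' Experiment configuration
#'
#' Bundles the cohort, sensors, scenarios and classifier settings shared by
#' the experiment drivers.  Defaults describe the emulated study: 10
#' subjects per group, 10 tasks in contiguous blocks for the separate
#' scenario (10 s windows), 9 tasks in 7 interleaved circuits for the mixed
#' scenario (4 s windows, no typing), one well-calibrated uniform-32 Hz g/64
#' device and one uneven-rate consumer device in g.
#'
#' @param n_subjects subjects per cohort.
#' @param heterogeneity cohort heterogeneity level (scalar or per-subject
#'   vector, see [make_cohort]).
#' @param k number of source subjects pooled per target (cross-subject /
#'   joint).
#' @param svm_C SVM cost parameter.
#' @param random_draws number of random source draws averaged in the
#'   baseline-selection arm.
#' @param sensor_source,sensor_target [sensor_model]s for the two devices.
#' @param scenario separate-task `scenario_spec` (source-side protocol).
#' @param scenario_target mixed-task `scenario_spec` (cross-scenario target).
#' @param window_source_s,window_target_s window lengths in seconds for the
#'   separate and mixed protocols.
#' @param shared_scenario_cohort if `TRUE` the cross-scenario target group is
#'   the same cohort as the source group, isolating task-dispersion as the
#'   only shift.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10, heterogeneity = 1, k = 5,
                              svm_C = 1, random_draws = 1,
                              sensor_source = sensor_uniform_g64(),
                              sensor_target = sensor_uneven_g(),
                              scenario = scenario_separate(),
                              scenario_target = scenario_mixed(),
                              window_source_s = 10, window_target_s = 4,
                              shared_scenario_cohort = FALSE) {
  stopifnot(n_subjects >= 2, k >= 1, k <= n_subjects - 1, random_draws >= 1,
            svm_C > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 heterogeneity = heterogeneity, k = as.integer(k),
                 svm_C = svm_C, random_draws = as.integer(random_draws),
                 sensor_source = sensor_source, sensor_target = sensor_target,
                 scenario = scenario, scenario_target = scenario_target,
                 window_source_s = window_source_s,
                 window_target_s = window_target_s,
                 shared_scenario_cohort = isTRUE(shared_scenario_cohort)),
            class = "experiment_config")
}

#' Simulate, preprocess and featurize one (subject, sensor, scenario) domain
#'
#' Runs the full front end: session simulation, unit conversion, gap-aware
#' resampling to 32 Hz, single-task windowing and DWT feature extraction.
#' The session seed depends only on (subject, scenario, seed), so calling
#' with two different sensor models yields two views of the same movement.
#'
#' @param subject a [subject_profile].
#' @param sensor a [sensor_model].
#' @param scenario a `scenario_spec`.
#' @param window_s window length in seconds.
#' @param seed integer seed.
#' @return An unstandardized labelled [domain_dataset].
#' @export
build_domain <- function(subject, sensor, scenario, window_s, seed = 1) {
  ses <- simulate_session(subject, sensor, scenario, seed = seed)
  rec <- regularize_sampling(convert_units(ses$recording), rate = 32,
                             max_gap = 1)
  wins <- segment_windows(rec, ses$annotations, window_s = window_s,
                          meta = list(subject = subject$subject_id,
                                      scenario = scenario$kind))
  features_from_windows(wins, meta = list(subject = subject$subject_id,
                                          sensor = sensor$sensor_id,
                                          scenario = scenario$kind,
                                          window_s = window_s))
}

pool_domains <- function(domains) {
  domain_dataset(do.call(rbind, lapply(domains, `[[`, "X")),
                 labels = unlist(lapply(domains, `[[`, "labels")),
                 meta = list(pooled = vapply(domains, function(d)
                   d$meta$subject, character(1))))
}

report_pair <- function(source, target, vocab, svm_C, rod_bar = NA_real_) {
  truth <- target$labels
  da <- evaluate(truth, fit_predict_da(source, target, svm_C = svm_C),
                 vocab, rod_bar = rod_bar)
  base <- evaluate(truth, fit_predict_baseline(source, target, svm_C = svm_C),
                   vocab, rod_bar = rod_bar)
  list(da = da, baseline = base)
}

experiment_result <- function(kind, reports, summary) {
  structure(list(kind = kind, reports = reports, summary = summary),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, digits = 3, ...) {
  cat(sprintf("<experiment_result> %s (%d targets)\n", x$kind,
              nrow(x$summary)))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

summary_row <- function(subject, pair, rod_all = NA_real_, rod_sel = NA_real_) {
  data.frame(subject = subject,
             acc_da = pair$da$accuracy,
             acc_baseline = pair$baseline$accuracy,
             f1_da = pair$da$overall_f1,
             f1_baseline = pair$baseline$overall_f1,
             rod_bar = rod_all,
             rod_bar_selected = rod_sel,
             stringsAsFactors = FALSE)
}

#' Cross-sensor experiment
#'
#' Within each subject, the well-calibrated device's windows are the
#' labelled source and the heterogeneous device's windows (same underlying
#' movement) are the unlabelled target; the adapted and baseline classifiers
#' are compared per subject.
#'
#' @param config an [experiment_config].
#' @param seed integer master seed.
#' @return An `experiment_result` with one (DA, baseline) report pair per
#'   subject.
#' @export
run_cross_sensor <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- make_cohort(config$n_subjects, config$heterogeneity,
                        seed = subseed(seed, 3L))
  vocab <- config$scenario$tasks
  reports <- list()
  rows <- list()
  for (i in seq_along(cohort)) {
    ses_seed <- subseed(seed, 5L, i)
    dsrc <- build_domain(cohort[[i]], config$sensor_source, config$scenario,
                         config$window_source_s, seed = ses_seed)
    dtgt <- build_domain(cohort[[i]], config$sensor_target, config$scenario,
                         config$window_source_s, seed = ses_seed)
    pair <- report_pair(dsrc, dtgt, vocab, config$svm_C)
    reports[[cohort[[i]]$subject_id]] <- pair
    rows[[i]] <- summary_row(cohort[[i]]$subject_id, pair)
  }
  experiment_result("cross-sensor", reports, do.call(rbind, rows))
}

# Shared state for the cross-subject-style experiments: cohort, one domain
# per subject per needed sensor, and the ROD value for every (target,
# candidate) pair (computed on per-domain standardized features at the
# SDM-selected dimension of each pair; ROD is symmetric so unordered pairs
# are cached).
cross_subject_state <- function(config, seed, target_sensor = NULL) {
  cohort <- make_cohort(config$n_subjects, config$heterogeneity,
                        seed = subseed(seed, 3L))
  n <- length(cohort)
  src <- lapply(seq_len(n), function(i) {
    build_domain(cohort[[i]], config$sensor_source, config$scenario,
                 config$window_source_s, seed = subseed(seed, 5L, i))
  })
  tgt <- if (is.null(target_sensor)) src else
    lapply(seq_len(n), function(i) {
      build_domain(cohort[[i]], target_sensor, config$scenario,
                   config$window_source_s, seed = subseed(seed, 5L, i))
    })
  std_src <- lapply(src, function(d) standardize(d)$X)
  std_tgt <- if (is.null(target_sensor)) std_src else
    lapply(tgt, function(d) standardize(d)$X)
  rods <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      if (is.null(target_sensor) && !is.na(rods[j, i])) {
        rods[i, j] <- rods[j, i]  # same-sensor ROD is symmetric
        next
      }
      rods[i, j] <- rod(std_src[[i]], std_tgt[[j]])$value
    }
  }
  list(cohort = cohort, source_domains = src, target_domains = tgt,
       rods = rods)
}

run_subject_style <- function(config, seed, target_sensor, kind) {
  stopifnot(inherits(config, "experiment_config"))
  st <- cross_subject_state(config, seed, target_sensor)
  n <- length(st$cohort)
  vocab <- config$scenario$tasks
  reports <- list()
  rows <- list()
  for (j in seq_len(n)) {
    cand <- setdiff(seq_len(n), j)
    rj <- st$rods[cand, j]
    sel <- cand[order(rj)][seq_len(config$k)]
    rod_all <- mean(rj)
    rod_sel <- mean(st$rods[sel, j])
    target <- st$target_domains[[j]]
    src_da <- pool_domains(st$source_domains[sel])
    da_rep <- evaluate(target$labels,
                       fit_predict_da(src_da, target, svm_C = config$svm_C),
                       vocab, rod_bar = rod_all)
    base_reps <- lapply(seq_len(config$random_draws), function(dr) {
      pick <- with_seed(subseed(seed, 7L, j, dr), sample(cand, config$k))
      src_rand <- pool_domains(st$source_domains[pick])
      evaluate(target$labels,
               fit_predict_baseline(src_rand, target, svm_C = config$svm_C),
               vocab, rod_bar = rod_all)
    })
    base_acc <- mean(vapply(base_reps, `[[`, numeric(1), "accuracy"))
    base_f1 <- vapply(base_reps, `[[`, numeric(1), "overall_f1")
    subject <- st$cohort[[j]]$subject_id
    reports[[subject]] <- list(da = da_rep, baseline = base_reps,
                               rods = rj, selected = sel)
    rows[[j]] <- data.frame(subject = subject,
                            acc_da = da_rep$accuracy,
                            acc_baseline = base_acc,
                            f1_da = da_rep$overall_f1,
                            f1_baseline = if (anyNA(base_f1)) NA_real_ else
                              mean(base_f1),
                            rod_bar = rod_all,
                            rod_bar_selected = rod_sel,
                            stringsAsFactors = FALSE)
  }
  experiment_result(kind, reports, do.call(rbind, rows))
}

#' Cross-subject experiment
#'
#' Each subject in turn is the unlabelled target; the k remaining subjects
#' with the lowest ROD to the target are pooled as the labelled source for
#' the DA arm, while the baseline arm pools k randomly selected subjects
#' (averaged over `random_draws`).  All domains come from the
#' well-calibrated device on the separate protocol.  The `rod_bar` column
#' is the mean ROD over all candidates; `rod_bar_selected` averages only the
#' chosen k.
#'
#' @inheritParams run_cross_sensor
#' @return An `experiment_result`.
#' @export
run_cross_subject <- function(config, seed = 1) {
  run_subject_style(config, seed, target_sensor = NULL, "cross-subject")
}

#' Joint cross-sensor and cross-subject experiment
#'
#' As [run_cross_subject], but the target is each subject's recording from
#' the heterogeneous device while the source pool still comes from the
#' well-calibrated device on the other subjects, so both shifts act at once.
#'
#' @inheritParams run_cross_sensor
#' @return An `experiment_result`.
#' @export
run_joint <- function(config, seed = 1) {
  run_subject_style(config, seed, target_sensor = config$sensor_target,
                    "joint cross-sensor + cross-subject")
}

#' Cross-scenario experiment
#'
#' Pooled separate-protocol windows (source group, 10 s windows) against
#' pooled mixed-protocol windows (target group, 4 s windows), both from the
#' well-calibrated device.  Typing is excluded from the vocabulary: it is
#' not performed in the mixed protocol, and source windows labelled typing
#' are dropped.
#'
#' @inheritParams run_cross_sensor
#' @return An `experiment_result` with a single pooled report pair.
#' @export
run_cross_scenario <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  vocab <- config$scenario_target$tasks
  if ("Tp" %in% vocab) stop("typing present in target scenario", call. = FALSE)
  src_cohort <- make_cohort(config$n_subjects, config$heterogeneity,
                            seed = subseed(seed, 3L))
  tgt_cohort <- if (config$shared_scenario_cohort) src_cohort else
    make_cohort(config$n_subjects, config$heterogeneity,
                seed = subseed(seed, 13L))
  src <- pool_domains(lapply(seq_along(src_cohort), function(i) {
    build_domain(src_cohort[[i]], config$sensor_source, config$scenario,
                 config$window_source_s, seed = subseed(seed, 5L, i))
  }))
  keep <- src$labels %in% vocab
  src <- domain_dataset(src$X[keep, , drop = FALSE], src$labels[keep],
                        meta = src$meta)
  tgt <- pool_domains(lapply(seq_along(tgt_cohort), function(i) {
    build_domain(tgt_cohort[[i]], config$sensor_source,
                 config$scenario_target, config$window_target_s,
                 seed = subseed(seed, 17L, i))
  }))
  if (!all(tgt$labels %in% vocab)) {
    stop("target annotations contain tasks outside the mixed vocabulary",
         call. = FALSE)
  }
  pair <- report_pair(src, tgt, vocab, config$svm_C)
  experiment_result("cross-scenario", list(pooled = pair),
                    summary_row("pooled", pair))
}

#' Sensitivity of the cross-subject comparison to k
#'
#' Re-runs the cross-subject selection for every k in `k_range`, reusing the
#' simulated domains and the ROD table, and reports per (k, arm) the mean
#' accuracy over subjects, the mean per-task F1 over all defined
#' (subject, task) cases, and the number of undefined per-task F1 cases that
#' had to be excluded from that mean.
#'
#' @param config an [experiment_config].
#' @param k_range integer vector of k values within `[1, n_subjects - 1]`.
#' @param seed integer master seed.
#' @return A `data.frame` of class `k_sensitivity` with `length(k_range) * 2`
#'   rows and columns `k`, `arm`, `mean_accuracy`, `mean_f1`,
#'   `excluded_cases`.
#' @export
sensitivity_k <- function(config, k_range, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(k_range) == 0L) stop("empty `k_range`", call. = FALSE)
  if (any(k_range < 1 | k_range > config$n_subjects - 1)) {
    stop("`k_range` must lie in [1, n_subjects - 1]", call. = FALSE)
  }
  st <- cross_subject_state(config, seed)
  n <- length(st$cohort)
  vocab <- config$scenario$tasks
  rows <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    acc <- list(da = numeric(n), baseline = numeric(n))
    f1s <- list(da = numeric(0), baseline = numeric(0))
    excl <- c(da = 0L, baseline = 0L)
    for (j in seq_len(n)) {
      cand <- setdiff(seq_len(n), j)
      sel <- cand[order(st$rods[cand, j])][seq_len(k)]
      pick <- with_seed(subseed(seed, 7L, j, 1L), sample(cand, k))
      target <- st$target_domains[[j]]
      preds <- list(
        da = fit_predict_da(pool_domains(st$source_domains[sel]), target,
                            svm_C = config$svm_C),
        baseline = fit_predict_baseline(pool_domains(st$source_domains[pick]),
                                        target, svm_C = config$svm_C))
      for (arm in names(preds)) {
        rep <- evaluate(target$labels, preds[[arm]], vocab)
        acc[[arm]][j] <- rep$accuracy
        excl[arm] <- excl[arm] + sum(is.na(rep$per_task_f1))
        f1s[[arm]] <- c(f1s[[arm]],
                        rep$per_task_f1[!is.na(rep$per_task_f1)])
      }
    }
    for (arm in c("da", "baseline")) {
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, arm = arm, mean_accuracy = mean(acc[[arm]]),
        mean_f1 = mean(f1s[[arm]]), excluded_cases = excl[[arm]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("k_sensitivity", "data.frame")
  out
}

#' Plot k-sensitivity curves
#'
#' @param x a `k_sensitivity` table.
#' @param metric `"mean_accuracy"` or `"mean_f1"`.
#' @param ... passed to [graphics::plot].
#' @export
plot.k_sensitivity <- function(x, metric = c("mean_accuracy", "mean_f1"), ...) {
  metric <- match.arg(metric)
  da <- x[x$arm == "da", ]
  ba <- x[x$arm == "baseline", ]
  ylim <- range(x[[metric]])
  graphics::plot(da$k, da[[metric]], type = "b", pch = 16, ylim = ylim,
                 xlab = "k source subjects", ylab = metric, ...)
  graphics::lines(ba$k, ba[[metric]], type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", c("GFK + SVM", "SVM"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
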