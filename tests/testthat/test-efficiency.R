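test_that("group cell means average participant means first", {
  trials <- dplyr::bind_rows(
    # participant 1: two trials averaging 600 in the one cell
    make_trial(participant_id = "P001", rt_ms = 590),
    make_trial(participant_id = "P001", rt_ms = 610, trial_index = 2),
    # participant 2: one trial at 620 (unequal trial counts must not bias)
    make_trial(participant_id = "P002", rt_ms = 620)
  )
  cells <- aggregate_condition_means(trials)
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$mean_rt_ms, 610)
  expect_equal(cells$se_rt_ms, sd(c(600, 620)) / sqrt(2)) # = 10
  expect_identical(cells$n, 2L)
})

test_that("degenerate cells are flagged, not fabricated", {
  single <- make_trial()
  cells <- aggregate_condition_means(single)
  expect_true(is.na(cells$se_rt_ms))
  expect_identical(cells$n, 1L)

  identical_rts <- dplyr::bind_rows(
    make_trial(participant_id = "P001"),
    make_trial(participant_id = "P002")
  )
  expect_equal(aggregate_condition_means(identical_rts)$se_rt_ms, 0)
})

test_that("exact log-linear points are recovered exactly", {
  ss <- c(1, 2, 5, 10, 20)
  f <- fit_log_efficiency(ss, 600 + 45 * log(ss))
  expect_equal(f$D, 45, tolerance = 1e-10)
  expect_equal(f$RT0, 600, tolerance = 1e-10)
  expect_equal(f$fit_r2, 1)

  flat <- fit_log_efficiency(ss, rep(700, 5))
  expect_equal(flat$D, 0, tolerance = 1e-12)
  expect_equal(flat$RT0, 700, tolerance = 1e-12)
})

test_that("fitting preconditions and the negative-slope warning hold", {
  expect_error(fit_log_efficiency(c(1, 1), c(600, 600)), "distinct")
  expect_error(fit_log_efficiency(c(2, 5, 10), c(650, 700, 730)), "target-only")
  expect_warning(
    fit_log_efficiency(c(1, 2, 5, 10, 20), 700 - 10 * log(c(1, 2, 5, 10, 20))),
    "negative"
  )
})

test_that("the slope is shift-invariant and scales with the data", {
  ss <- c(1, 2, 5, 10, 20)
  rts <- 620 + 70 * log(ss) + c(3, -5, 2, -1, 4) # mild non-log-linear noise
  base <- fit_log_efficiency(ss, rts)
  shifted <- fit_log_efficiency(ss, rts + 150)
  expect_equal(shifted$D, base$D, tolerance = 1e-10)
  expect_equal(shifted$RT0, base$RT0 + 150, tolerance = 1e-10)
  scaled <- fit_log_efficiency(ss, rts * 3)
  expect_equal(scaled$D, base$D * 3, tolerance = 1e-10)
})

test_that("reference rows regenerate their set-size-20 RT through the fitted law", {
  ref <- reference_single_feature()
  ss <- c(1, 2, 5, 10, 20)
  for (i in seq_len(nrow(ref))) {
    rt0 <- ref$rt_set_size_20[i] - ref$D[i] * log(20)
    f <- fit_log_efficiency(ss, rt0 + ref$D[i] * log(ss))
    expect_equal(f$D, ref$D[i], tolerance = 1e-10)
    expect_equal(f$RT0 + f$D * log(20), ref$rt_set_size_20[i], tolerance = 1e-8)
  }
})

test_that("experiment-level fitting shares the target-only point across conditions", {
  setup <- study_design("1B", trial_noise_sd = 0, error_rate = 0, timeout_rate = 0,
                        between_participant_RT0_sd = 0, seed = 4)
  sim <- simulate_experiment(setup$design, setup$params)
  filt <- filter_trials(
    sim$trials,
    apply_exclusions(summarize_participants(sim$trials))
  )
  eff <- fit_experiment_efficiencies(aggregate_condition_means(filt))
  expect_identical(nrow(eff), 3L)
  got <- setNames(eff$D, eff$distractor_texture)
  expect_equal(got[c("solid", "tilted_pound", "dots")],
    c(solid = 43.9, tilted_pound = 111.9, dots = 69.5),
    tolerance = 1e-8
  )
  expect_equal(eff$RT0, rep(setup$params$true_RT0_mean, 3), tolerance = 1e-8)
  expect_true(all(vapply(
    eff$cells, function(cc) identical(cc$total_set_size, c(1L, 2L, 5L, 10L, 20L)),
    logical(1)
  )))
})

test_that("the per-participant sensitivity fit agrees on noise-free data", {
  setup <- study_design("1A", trial_noise_sd = 0, error_rate = 0, timeout_rate = 0,
                        between_participant_RT0_sd = 25, seed = 6)
  sim <- simulate_experiment(setup$design, setup$params)
  filt <- filter_trials(
    sim$trials,
    apply_exclusions(summarize_participants(sim$trials))
  )
  group <- fit_experiment_efficiencies(aggregate_condition_means(filt))
  per <- fit_experiment_efficiencies(filt, method = "per_participant")
  merged <- dplyr::inner_join(
    group[, c("distractor_shape", "D")],
    per[, c("distractor_shape", "D")],
    by = "distractor_shape", suffix = c("_group", "_per")
  )
  expect_equal(merged$D_group, merged$D_per, tolerance = 1e-8)
})
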