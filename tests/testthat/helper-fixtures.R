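# Shared fixture builders: all tables are generated in code at test time.

# One valid trial row with overridable fields.
make_trial <- function(participant_id = "P001", experiment_id = "1A",
                       distractor_shape = "house", distractor_texture = "cross",
                       n_distractors = 4L, rt_ms = 700, correct = TRUE,
                       timed_out = FALSE, trial_index = 1L) {
  tibble::tibble(
    participant_id = participant_id,
    experiment_id = experiment_id,
    condition_id = condition_label(distractor_shape, distractor_texture, n_distractors),
    distractor_shape = distractor_shape,
    distractor_texture = distractor_texture,
    n_distractors = as.integer(n_distractors),
    total_set_size = as.integer(n_distractors) + 1L,
    trial_index = as.integer(trial_index),
    rt_ms = rt_ms,
    correct = correct,
    timed_out = timed_out
  )
}

# A random valid trial table, mixing distractor and target-only rows,
# occasional errors and timeouts.
random_trial_table <- function(n = 50, seed = 42, participant_id = "P001") {
  set.seed(seed)
  shapes <- c("house", "square", "triangle")
  textures <- c("cross", "dots", "solid")
  rows <- lapply(seq_len(n), function(i) {
    target_only <- runif(1) < 0.15
    timed_out <- runif(1) < 0.05
    correct <- !timed_out & runif(1) > 0.05
    make_trial(
      participant_id = participant_id,
      distractor_shape = if (target_only) "none" else sample(shapes, 1),
      distractor_texture = if (target_only) "none" else sample(textures, 1),
      n_distractors = if (target_only) 0L else sample(c(1L, 4L, 9L, 19L), 1),
      rt_ms = if (timed_out) 5000 else round(runif(1, 300, 1500), 1),
      correct = correct,
      timed_out = timed_out,
      trial_index = i
    )
  })
  dplyr::bind_rows(rows)
}

# A deterministic single-condition design for fast generator tests.
tiny_design <- function(reps = 4L) {
  experiment_design(
    "T1",
    distractor_conditions = tibble::tibble(shape = "house", texture = "dots"),
    reps_per_condition = reps
  )
}

tiny_params <- function(...) {
  generating_params(
    true_D = c(house_dots = 45),
    true_RT0_mean = 600,
    ...
  )
}

# Participant summaries drawn around a common mean RT, for exclusion tests.
make_summaries <- function(mean_rts, accuracies = NULL,
                           ids = sprintf("P%03d", seq_along(mean_rts))) {
  if (is.null(accuracies)) accuracies <- rep(0.98, length(mean_rts))
  tibble::tibble(
    participant_id = ids,
    n_trials = 624L,
    n_correct = as.integer(round(624 * accuracies)),
    accuracy = accuracies,
    mean_rt_ms = mean_rts
  )
}

# Fit slopes of every condition of one simulated, screened experiment;
# returns a vector named by "<shape>_<texture>".
fitted_experiment_Ds <- function(experiment_id, seed, ...) {
  setup <- study_design(experiment_id, seed = seed, ...)
  sim <- simulate_experiment(setup$design, setup$params)
  scr <- apply_exclusions(summarize_participants(sim$trials))
  filt <- filter_trials(sim$trials, scr)
  eff <- fit_experiment_efficiencies(aggregate_condition_means(filt))
  stats::setNames(
    eff$D, paste(eff$distractor_shape, eff$distractor_texture, sep = "_")
  )
}
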