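#' Generating parameters for a synthetic search cohort
#'
#' The generator produces RTs from the logarithmic efficiency law
#' `RT = RT0_i + D(condition) * ln(total set size) + eps`, where `RT0_i` is a
#' participant-level intercept drawn once per participant around
#' `true_RT0_mean`, and `eps` is zero-mean Gaussian trial noise truncated
#' below at a motor floor (150 ms) so no impossible RTs occur. A trial is
#' independently a timeout (stored at the deadline, incorrect) with
#' probability `timeout_rate`, otherwise an error with probability
#' `error_rate`; error trials keep their law-generated RT since downstream
#' analysis discards them.
#'
#' Defaults emulate the reference cohorts: ~1.5% errors (group accuracies of
#' 0.98-0.99), rare timeouts, 100 ms trial noise and a 50 ms
#' between-participant intercept spread (together giving participant mean-RT
#' spreads near the 80-110 ms reported group SDs), and a target of 20
#' included participants.
#'
#' @param true_D Named numeric vector of generating slopes (ms per ln-unit),
#'   one per distractor pairing, named `"<shape>_<texture>"`.
#' @param true_RT0_mean Group-mean target-only intercept, ms.
#' @param between_participant_RT0_sd SD of the participant intercepts, ms.
#' @param trial_noise_sd SD of Gaussian trial noise, ms.
#' @param error_rate,timeout_rate Per-trial probabilities; their sum must be
#'   below 1.
#' @param n_included_target Participants that must pass screening before data
#'   collection stops.
#' @param rt_floor_ms Lower truncation bound for generated RTs, ms.
#' @param seed Master seed for [simulate_experiment()].
#' @return A `generating_params` list.
#' @export
generating_params <- function(true_D,
                              true_RT0_mean,
                              between_participant_RT0_sd = 50,
                              trial_noise_sd = 100,
                              error_rate = 0.015,
                              timeout_rate = 0.002,
                              n_included_target = 20L,
                              rt_floor_ms = .RT_FLOOR_MS,
                              seed = 1L) {
  stopifnot(
    is.numeric(true_D), length(true_D) >= 1, !is.null(names(true_D)),
    all(true_D >= 0),
    is.numeric(true_RT0_mean), true_RT0_mean > 0,
    between_participant_RT0_sd >= 0, trial_noise_sd >= 0,
    error_rate >= 0, error_rate < 1,
    timeout_rate >= 0, timeout_rate < 1,
    error_rate + timeout_rate < 1,
    n_included_target >= 1, rt_floor_ms > 0
  )
  structure(
    list(
      true_D = true_D,
      true_RT0_mean = true_RT0_mean,
      between_participant_RT0_sd = between_participant_RT0_sd,
      trial_noise_sd = trial_noise_sd,
      error_rate = error_rate,
      timeout_rate = timeout_rate,
      n_included_target = as.integer(n_included_target),
      rt_floor_ms = rt_floor_ms,
      seed = as.integer(seed)
    ),
    class = "generating_params"
  )
}

#' Simulate one participant's session
#'
#' Generates the full trial table of one participant under a design and
#' generating parameters, using the current RNG state (callers control
#' reproducibility by seeding; [simulate_experiment()] gives each participant
#' its own counter-derived substream). Presentation order is randomized.
#'
#' @param design An [experiment_design()].
#' @param params [generating_params()]; every distractor pairing in the
#'   design must have a generating slope.
#' @param participant_id Identifier stored on each row.
#' @param rt0 Participant intercept, ms; drawn from
#'   `Normal(true_RT0_mean, between_participant_RT0_sd)` when `NULL`.
#' @return A validated trial tibble of `design$trials_per_participant` rows.
#' @export
simulate_participant <- function(design, params, participant_id, rt0 = NULL) {
  grid <- design_condition_grid(design)
  keys <- pairing_key(grid$distractor_shape, grid$distractor_texture)
  need <- setdiff(unique(keys[grid$n_distractors > 0L]), names(params$true_D))
  if (length(need) > 0) {
    stop("no generating slope for pairing(s): ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(rt0)) {
    rt0 <- rnorm(1, params$true_RT0_mean, params$between_participant_RT0_sd)
  }

  trials <- grid[rep(seq_len(nrow(grid)), each = design$reps_per_condition), ]
  n <- nrow(trials)
  trials <- trials[sample.int(n), ]

  D <- ifelse(trials$n_distractors == 0L, 0,
    params$true_D[pairing_key(trials$distractor_shape, trials$distractor_texture)]
  )
  rt <- rt0 + D * log(trials$total_set_size) + rnorm(n, 0, params$trial_noise_sd)
  rt <- pmax(rt, params$rt_floor_ms)

  u <- runif(n)
  timed_out <- u < params$timeout_rate
  errored <- !timed_out & u < params$timeout_rate + params$error_rate
  rt[timed_out] <- design$deadline_ms

  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    experiment_id = design$experiment_id,
    condition_id = trials$condition_id,
    distractor_shape = trials$distractor_shape,
    distractor_texture = trials$distractor_texture,
    n_distractors = trials$n_distractors,
    total_set_size = trials$total_set_size,
    trial_index = seq_len(n),
    rt_ms = rt,
    correct = !timed_out & !errored,
    timed_out = timed_out
  )
  validate_trials(out, deadline_ms = design$deadline_ms)
}

#' Simulate an experiment with sequential participant screening
#'
#' Candidates are generated one at a time and screened against the running
#' group, mirroring a stopping rule in which data collection ends as soon as
#' the target number of participants passes both inclusion criteria: accuracy
#' strictly above `accuracy_min`, and (once at least `min_group` accuracy-
#' passing candidates exist) a mean correct-trial RT within `rt_sd_k` SDs of
#' the accuracy-passing group's mean (candidate included in the group
#' statistics). All generated candidates, included or not, are returned.
#'
#' Reproducibility: the master seed drives a counter of per-participant
#' substream seeds, so cohorts are deterministic given `params$seed` and
#' participants are mutually independent.
#'
#' @param design An [experiment_design()].
#' @param params [generating_params()] with the master `seed`.
#' @param accuracy_min,rt_sd_k Screening thresholds (see [apply_exclusions()]).
#' @param min_group Accuracy-passing candidates required before the RT rule
#'   activates.
#' @param max_candidates Safety cap; exceeding it raises an error indicating
#'   that the parameters make inclusion improbable. Defaults to 10x the
#'   inclusion target.
#' @return A list with `trials` (all candidates' rows) and `truth`: the
#'   per-condition generating slopes and intercept, per-participant realized
#'   intercepts and screening outcomes, and the seed.
#' @export
simulate_experiment <- function(design, params,
                                accuracy_min = 0.90, rt_sd_k = 2.0,
                                min_group = 5L,
                                max_candidates = 10L * params$n_included_target) {
  set.seed(params$seed)
  substream_seeds <- sample.int(.Machine$integer.max, max_candidates)

  trials <- vector("list", max_candidates)
  part <- tibble::tibble(
    participant_id = character(), rt0 = double(), accuracy = double(),
    mean_rt_ms = double(), included = logical(), exclusion_reason = character()
  )
  n_included <- 0L
  k <- 0L
  while (n_included < params$n_included_target && k < max_candidates) {
    k <- k + 1L
    pid <- sprintf("%s_P%03d", design$experiment_id, k)
    set.seed(substream_seeds[k])
    rt0_k <- rnorm(1, params$true_RT0_mean, params$between_participant_RT0_sd)
    tr <- simulate_participant(design, params, pid, rt0 = rt0_k)
    trials[[k]] <- tr

    acc <- mean(tr$correct)
    ok_rt <- tr$correct & !tr$timed_out
    mrt <- if (any(ok_rt)) mean(tr$rt_ms[ok_rt]) else NA_real_

    if (!(acc > accuracy_min)) {
      reason <- "low_accuracy"
    } else {
      passing <- c(part$mean_rt_ms[part$accuracy > accuracy_min], mrt)
      if (length(passing) < min_group) {
        reason <- "none"
      } else {
        m <- mean(passing)
        s <- sd(passing)
        reason <- if (s > 0 && abs(mrt - m) > rt_sd_k * s) "rt_outlier" else "none"
      }
    }
    included <- reason == "none"
    if (included) n_included <- n_included + 1L
    part <- dplyr::bind_rows(part, tibble::tibble(
      participant_id = pid, rt0 = rt0_k, accuracy = acc,
      mean_rt_ms = mrt, included = included, exclusion_reason = reason
    ))
  }
  if (n_included < params$n_included_target) {
    stop(sprintf(
      "only %d of %d target participants passed screening after %d candidates; generating parameters make inclusion improbable",
      n_included, params$n_included_target, max_candidates
    ), call. = FALSE)
  }

  truth <- list(
    conditions = tibble::tibble(
      pairing = names(params$true_D),
      true_D = unname(params$true_D),
      true_RT0 = params$true_RT0_mean
    ),
    participants = part,
    seed = params$seed,
    params = params
  )
  list(trials = dplyr::bind_rows(trials[seq_len(k)]), truth = truth)
}
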