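#' Column set of a trial-level search table
#'
#' All stages of the pipeline consume long-format trial tables with exactly
#' these columns, in this order. One row is one search trial.
#'
#' @return Character vector of column names.
#' @export
trial_columns <- function() {
  c(
    "participant_id", "experiment_id", "condition_id",
    "distractor_shape", "distractor_texture",
    "n_distractors", "total_set_size", "trial_index",
    "rt_ms", "correct", "timed_out"
  )
}

#' Condition label for a distractor type at a given set size
#'
#' Condition identity is carried by the distractor's shape and texture plus
#' the distractor count; the target-only condition (no distractors) gets the
#' fixed label `"target_only"`. The target's own shape and texture never vary
#' within an experiment and are not stored per row.
#'
#' @param shape,texture Distractor shape and texture (`"none"` when absent).
#' @param n_distractors Number of distractors on the display.
#' @return Character vector of condition labels.
#' @export
condition_label <- function(shape, texture, n_distractors) {
  ifelse(n_distractors == 0L, "target_only",
    sprintf("%s_%s_n%02d", shape, texture, n_distractors)
  )
}

# Distractor-type key (shape x texture), ignoring set size. Used to index
# generating slopes and fitted efficiencies.
pairing_key <- function(shape, texture) paste(shape, texture, sep = "_")

#' Validate a trial table against the data-model invariants
#'
#' Checks, row by row: known shape/texture levels; distractor counts in
#' \{0, 1, 4, 9, 19\}; `total_set_size == n_distractors + 1` (total set size
#' counts all distractors plus the target); `0 < rt_ms <= deadline` for
#' responded trials; timeouts stored with `rt_ms` equal to the deadline and
#' `correct = FALSE`; and the target-only condition encoded consistently
#' (`n_distractors == 0` iff both shape and texture are `"none"`).
#'
#' @param trials A data frame with the columns of [trial_columns()].
#' @param deadline_ms Response deadline in milliseconds.
#' @return `trials` invisibly, as a tibble, if all checks pass.
#' @export
validate_trials <- function(trials, deadline_ms = .DEADLINE_MS) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_columns(), names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(names(trials), trial_columns())
  if (length(unknown) > 0) {
    stop("trial table has unknown column(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  fail <- function(rows, rule) {
    stop(sprintf(
      "trial validation failed at row(s) %s: %s",
      paste(head(rows, 5L), collapse = ", "), rule
    ), call. = FALSE)
  }
  bad <- which(!trials$distractor_shape %in% .SHAPES)
  if (length(bad)) fail(bad, "unknown distractor_shape")
  bad <- which(!trials$distractor_texture %in% .TEXTURES)
  if (length(bad)) fail(bad, "unknown distractor_texture")
  bad <- which(!trials$n_distractors %in% .DISTRACTOR_COUNTS)
  if (length(bad)) fail(bad, "n_distractors must be one of 0, 1, 4, 9, 19")
  bad <- which(trials$total_set_size != trials$n_distractors + 1L)
  if (length(bad)) fail(bad, "total_set_size must equal n_distractors + 1")
  bad <- which(trials$trial_index < 1L)
  if (length(bad)) fail(bad, "trial_index must be >= 1")
  bad <- which(!(trials$rt_ms > 0))
  if (length(bad)) fail(bad, "rt_ms must be positive")
  bad <- which(!trials$timed_out & trials$rt_ms > deadline_ms)
  if (length(bad)) fail(bad, sprintf("rt_ms exceeds the %g ms deadline on a non-timeout trial", deadline_ms))
  bad <- which(trials$timed_out & (trials$rt_ms != deadline_ms | trials$correct))
  if (length(bad)) fail(bad, "timeout rows must have rt_ms equal to the deadline and correct = FALSE")
  none_shape <- trials$distractor_shape == "none"
  none_texture <- trials$distractor_texture == "none"
  target_only <- trials$n_distractors == 0L
  bad <- which(none_shape != target_only | none_texture != target_only)
  if (length(bad)) fail(bad, "n_distractors == 0 iff distractor_shape and distractor_texture are 'none'")

  invisible(trials)
}

#' Read a trial-level CSV
#'
#' Reads the long-format trial table written by [write_trials()] (comma
#' separated, UTF-8, `.` decimal, header mandatory, booleans as
#' `"true"`/`"false"`) and validates every row. `read_trials()` after
#' [write_trials()] is the identity on valid tables.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(trial_columns(), header)
  if (length(missing) > 0) {
    stop("trials CSV is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(header, trial_columns())
  if (length(unknown) > 0) {
    stop("trials CSV has unknown column(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      experiment_id = readr::col_character(),
      condition_id = readr::col_character(),
      distractor_shape = readr::col_character(),
      distractor_texture = readr::col_character(),
      n_distractors = readr::col_integer(),
      total_set_size = readr::col_integer(),
      trial_index = readr::col_integer(),
      rt_ms = readr::col_double(),
      correct = readr::col_logical(),
      timed_out = readr::col_logical()
    ),
    show_col_types = FALSE
  )
  trials <- trials[, trial_columns()]
  validate_trials(trials)
  trials
}

#' Write a trial-level CSV
#'
#' @param trials A validated trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) == 0) stop("refusing to write an empty trial table", call. = FALSE)
  trials <- validate_trials(trials)
  out <- trials[, trial_columns()]
  out$correct <- ifelse(out$correct, "true", "false")
  out$timed_out <- ifelse(out$timed_out, "true", "false")
  readr::write_csv(out, path)
  invisible(path)
}

#' Describe an experiment's condition structure
#'
#' An experiment crosses a small set of homogeneous distractor types with a
#' fixed set of distractor counts, plus one shared target-only condition.
#' Under the default design (3 distractor types x counts 1, 4, 9, 19, plus
#' target-only, 48 repetitions each) a participant contributes
#' 13 x 48 = 624 trials.
#'
#' @param experiment_id Experiment label, e.g. `"1A"`.
#' @param distractor_conditions Data frame with columns `shape` and `texture`,
#'   one row per distractor type.
#' @param distractor_set_sizes Distractor counts of the non-empty displays.
#' @param include_target_only Include the shared zero-distractor condition?
#' @param reps_per_condition Repetitions of each condition per participant.
#' @param deadline_ms Response deadline in milliseconds.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(experiment_id,
                              distractor_conditions,
                              distractor_set_sizes = c(1L, 4L, 9L, 19L),
                              include_target_only = TRUE,
                              reps_per_condition = 48L,
                              deadline_ms = .DEADLINE_MS) {
  distractor_conditions <- tibble::as_tibble(distractor_conditions)
  stopifnot(
    all(c("shape", "texture") %in% names(distractor_conditions)),
    nrow(distractor_conditions) >= 1,
    all(distractor_set_sizes %in% setdiff(.DISTRACTOR_COUNTS, 0L)),
    reps_per_condition >= 1, deadline_ms > 0
  )
  if (any(distractor_conditions$shape == "none") ||
    any(distractor_conditions$texture == "none")) {
    stop("distractor conditions may not use the reserved level 'none'", call. = FALSE)
  }
  design <- list(
    experiment_id = as.character(experiment_id),
    distractor_conditions = distractor_conditions,
    distractor_set_sizes = as.integer(sort(distractor_set_sizes)),
    include_target_only = isTRUE(include_target_only),
    reps_per_condition = as.integer(reps_per_condition),
    deadline_ms = deadline_ms
  )
  design$n_conditions <- nrow(distractor_conditions) * length(design$distractor_set_sizes) +
    as.integer(design$include_target_only)
  design$trials_per_participant <- design$n_conditions * design$reps_per_condition
  structure(design, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Experiment %s: %d distractor type(s) x counts {%s}%s = %d conditions, %d reps, %d trials/participant\n",
    x$experiment_id, nrow(x$distractor_conditions),
    paste(x$distractor_set_sizes, collapse = ", "),
    if (x$include_target_only) " + target-only" else "",
    x$n_conditions, x$reps_per_condition, x$trials_per_participant
  ))
  invisible(x)
}

# Expand a design into its per-trial condition grid (one row per trial,
# before randomizing presentation order).
design_condition_grid <- function(design) {
  cond <- design$distractor_conditions
  grid <- tidyr::expand_grid(
    type = seq_len(nrow(cond)),
    n_distractors = design$distractor_set_sizes
  )
  grid <- tibble::tibble(
    distractor_shape = cond$shape[grid$type],
    distractor_texture = cond$texture[grid$type],
    n_distractors = as.integer(grid$n_distractors)
  )
  if (design$include_target_only) {
    grid <- dplyr::bind_rows(
      tibble::tibble(
        distractor_shape = "none", distractor_texture = "none",
        n_distractors = 0L
      ),
      grid
    )
  }
  grid$total_set_size <- grid$n_distractors + 1L
  grid$condition_id <- condition_label(
    grid$distractor_shape, grid$distractor_texture, grid$n_distractors
  )
  grid
}

#' Check a trial table against its intended design
#'
#' Deviations (missing conditions, wrong repetition counts, unexpected
#' conditions) are reported per participant, never raised as errors.
#'
#' @param trials Trial table from a single experiment.
#' @param design The intended [experiment_design()].
#' @return A list with `summary` (one row per participant: conditions seen,
#'   total trials, deviation count) and `deviations` (one row per
#'   participant x condition that departs from the design).
#' @export
validate_design <- function(trials, design) {
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) > 0 && length(unique(trials$experiment_id)) > 1) {
    stop("validate_design expects trials from a single experiment", call. = FALSE)
  }
  expected <- design_condition_grid(design)
  expected_counts <- tibble::tibble(
    condition_id = unique(expected$condition_id),
    expected_reps = design$reps_per_condition
  )

  if (nrow(trials) == 0) {
    return(list(
      summary = tibble::tibble(
        participant_id = character(), n_conditions = integer(),
        n_trials = integer(), n_deviations = integer()
      ),
      deviations = tibble::tibble(
        participant_id = character(), condition_id = character(),
        expected_reps = integer(), observed_reps = integer(), note = character()
      )
    ))
  }

  observed <- trials |>
    dplyr::count(.data$participant_id, .data$condition_id, name = "observed_reps")
  per_part <- observed |>
    tidyr::complete(
      participant_id = unique(trials$participant_id),
      condition_id = expected_counts$condition_id,
      fill = list(observed_reps = 0L)
    ) |>
    dplyr::left_join(expected_counts, by = "condition_id")
  # conditions absent from the design show expected_reps = NA
  per_part$expected_reps[is.na(per_part$expected_reps)] <- 0L

  deviations <- per_part |>
    dplyr::filter(.data$observed_reps != .data$expected_reps) |>
    dplyr::mutate(note = dplyr::case_when(
      .data$expected_reps == 0L ~ "condition not in design",
      .data$observed_reps == 0L ~ "condition missing",
      TRUE ~ "repetition count differs"
    )) |>
    dplyr::select(
      "participant_id", "condition_id",
      "expected_reps", "observed_reps", "note"
    )

  summary <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_conditions = dplyr::n_distinct(.data$condition_id),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      deviations |> dplyr::count(.data$participant_id, name = "n_deviations"),
      by = "participant_id"
    ) |>
    dplyr::mutate(n_deviations = dplyr::coalesce(.data$n_deviations, 0L))

  list(summary = summary, deviations = deviations)
}
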