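#' Per-participant accuracy and mean-RT summaries
#'
#' Accuracy is the proportion of correct trials out of all trials, with
#' timeouts counting as incorrect; mean RT is taken over correct, non-timeout
#' trials only and is `NA` when a participant has none (flagged downstream as
#' unscreenable on RT).
#'
#' @param trials Trial table (one or more participants).
#' @return A tibble, one row per participant: `participant_id`, `n_trials`,
#'   `n_correct`, `accuracy`, `mean_rt_ms`.
#' @export
summarize_participants <- function(trials) {
  if (nrow(tibble::as_tibble(trials)) == 0) {
    stop("cannot summarize an empty trial table", call. = FALSE)
  }
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      accuracy = mean(.data$correct),
      mean_rt_ms = {
        ok <- .data$correct & !.data$timed_out
        if (any(ok)) mean(.data$rt_ms[ok]) else NA_real_
      },
      .groups = "drop"
    )
}

#' Apply the participant inclusion criteria
#'
#' Two rules, applied once, in order: (1) participants whose accuracy is not
#' strictly above `accuracy_min` are excluded (`low_accuracy`; exactly 90% is
#' excluded); (2) among the accuracy-passing participants, the group mean and
#' SD of the individual mean RTs are computed and participants farther than
#' `rt_sd_k` SDs from the group mean are excluded (`rt_outlier`). The
#' candidate's own mean enters the group statistics (`leave_one_in = TRUE`,
#' the default); set `FALSE` to score each participant against the group
#' excluding them.
#'
#' @param summaries Output of [summarize_participants()] (at least 2 rows).
#' @param accuracy_min Accuracy must exceed this proportion.
#' @param rt_sd_k Width of the RT inclusion band, in group SDs.
#' @param leave_one_in Include the candidate in the group mean/SD?
#' @return `summaries` with `included` and `exclusion_reason`
#'   (`"none"`, `"low_accuracy"`, `"rt_outlier"`) appended.
#' @export
apply_exclusions <- function(summaries, accuracy_min = 0.90, rt_sd_k = 2.0,
                             leave_one_in = TRUE) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) < 2) {
    stop("apply_exclusions needs at least 2 participants", call. = FALSE)
  }
  acc_pass <- summaries$accuracy > accuracy_min
  reason <- ifelse(acc_pass, "none", "low_accuracy")

  mrt <- summaries$mean_rt_ms
  idx <- which(acc_pass)
  if (length(idx) >= 2) {
    for (i in idx) {
      group <- if (leave_one_in) mrt[idx] else mrt[setdiff(idx, i)]
      m <- mean(group)
      s <- sd(group)
      if (is.na(mrt[i]) ||
        (isTRUE(s > 0) && abs(mrt[i] - m) > rt_sd_k * s)) {
        reason[i] <- "rt_outlier"
      }
    }
  }
  summaries$included <- reason == "none"
  summaries$exclusion_reason <- reason
  summaries
}

#' Keep analyzable trials
#'
#' Retains only trials from included participants that are correct and not
#' timeouts; only those RTs enter the efficiency fits.
#'
#' @param trials Trial table.
#' @param included Character vector of included participant ids, or the
#'   output of [apply_exclusions()] (its included ids are used).
#' @return The filtered trial tibble.
#' @export
filter_trials <- function(trials, included) {
  if (is.data.frame(included)) {
    included <- included$participant_id[included$included]
  }
  trials |>
    dplyr::filter(
      .data$participant_id %in% included,
      .data$correct,
      !.data$timed_out
    )
}
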