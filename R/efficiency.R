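#' Group mean RTs per condition and set size
#'
#' Two-stage aggregation: the mean RT of each participant in each
#' condition x set-size cell is computed first, then the group mean is the
#' mean of those participant means, the SE their SD divided by sqrt(n), and
#' `n` the number of contributing participants. The SE is `NA` with a single
#' participant, and cells with no trials are simply absent.
#'
#' @param trials Filtered trials (correct, non-timeout, included
#'   participants; see [filter_trials()]).
#' @return A tibble keyed by `experiment_id`, `distractor_shape`,
#'   `distractor_texture`, `total_set_size`, with `mean_rt_ms`, `se_rt_ms`,
#'   `n`.
#' @export
aggregate_condition_means <- function(trials) {
  trials |>
    dplyr::group_by(
      .data$experiment_id, .data$distractor_shape, .data$distractor_texture,
      .data$total_set_size, .data$participant_id
    ) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    dplyr::group_by(
      .data$experiment_id, .data$distractor_shape, .data$distractor_texture,
      .data$total_set_size
    ) |>
    dplyr::summarise(
      mean_rt_ms = mean(.data$rt),
      se_rt_ms = sd(.data$rt) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit the logarithmic efficiency law to one condition
#'
#' Ordinary least squares of mean RT on the natural log of total set size:
#' the slope is the search efficiency D (ms per ln-unit; steeper = less
#' efficient search) and the intercept is RT0, the target-only response time.
#' Under the reference design the points are the five total set sizes
#' \{1, 2, 5, 10, 20\}. The fit is unweighted.
#'
#' @param set_sizes Total set sizes (must include 1, the target-only display).
#' @param mean_rts Group mean RTs, ms, aligned with `set_sizes`.
#' @return A list: `D`, `RT0`, `fit_r2`, `n_points`. A negative fitted D is
#'   permitted but warned about (the efficiency law expects D >= 0).
#' @export
fit_log_efficiency <- function(set_sizes, mean_rts) {
  stopifnot(length(set_sizes) == length(mean_rts))
  if (length(unique(set_sizes)) < 2) {
    stop("need at least 2 distinct set sizes to fit a slope", call. = FALSE)
  }
  if (!1 %in% set_sizes) {
    stop("the target-only point (total set size 1) is required", call. = FALSE)
  }
  fit <- lm(mean_rts ~ log(set_sizes))
  D <- unname(coef(fit)[2])
  RT0 <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  tss <- sum((mean_rts - mean(mean_rts))^2)
  # flat data fit exactly by a zero slope: define R^2 = 1 when residuals vanish
  fit_r2 <- if (rss < 1e-10) 1 else 1 - rss / tss
  if (D < 0) {
    warning(sprintf("fitted efficiency slope is negative (D = %.2f ms/ln-unit)", D),
      call. = FALSE
    )
  }
  list(D = D, RT0 = RT0, fit_r2 = fit_r2, n_points = length(set_sizes))
}

#' Fit efficiencies for every condition of an experiment
#'
#' For each distractor pairing, combines that pairing's per-set-size group
#' means with the experiment's shared target-only mean (total set size 1,
#' which enters every condition's fit) and runs [fit_log_efficiency()].
#'
#' With `method = "per_participant"` the law is instead fitted per
#' participant on their own cell means and the slopes and intercepts averaged
#' across participants — a sensitivity variant; group means remain the
#' default.
#'
#' @param cell_means Output of [aggregate_condition_means()] for a single
#'   experiment — or, for the per-participant method, the filtered trials
#'   themselves.
#' @param method `"group_means"` (default) or `"per_participant"`.
#' @return A tibble: `experiment_id`, `distractor_shape`,
#'   `distractor_texture`, `D`, `RT0`, `fit_r2`, and a `cells` list-column of
#'   the per-set-size means used.
#' @export
fit_experiment_efficiencies <- function(cell_means, method = c("group_means", "per_participant")) {
  method <- match.arg(method)
  if (method == "per_participant") {
    return(fit_efficiencies_per_participant(cell_means))
  }
  cell_means <- tibble::as_tibble(cell_means)
  if (length(unique(cell_means$experiment_id)) != 1) {
    stop("cell means must come from a single experiment", call. = FALSE)
  }
  target_only <- cell_means[cell_means$total_set_size == 1, ]
  if (nrow(target_only) != 1) {
    stop("expected exactly one target-only cell (total set size 1)", call. = FALSE)
  }
  distract <- cell_means[cell_means$total_set_size > 1, ]
  pairs <- dplyr::distinct(
    distract, .data$experiment_id, .data$distractor_shape, .data$distractor_texture
  )
  purrr::pmap_dfr(pairs, function(experiment_id, distractor_shape, distractor_texture) {
    cells <- distract[
      distract$distractor_shape == distractor_shape &
        distract$distractor_texture == distractor_texture,
    ]
    cells <- dplyr::bind_rows(target_only, cells) |>
      dplyr::arrange(.data$total_set_size)
    f <- fit_log_efficiency(cells$total_set_size, cells$mean_rt_ms)
    tibble::tibble(
      experiment_id = experiment_id,
      distractor_shape = distractor_shape,
      distractor_texture = distractor_texture,
      D = f$D, RT0 = f$RT0, fit_r2 = f$fit_r2,
      cells = list(cells)
    )
  })
}

# Sensitivity variant: one fit per participant per condition, coefficients
# averaged across participants.
fit_efficiencies_per_participant <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if (!"participant_id" %in% names(trials) || !"rt_ms" %in% names(trials)) {
    stop("per-participant fitting needs the filtered trial table", call. = FALSE)
  }
  pp <- trials |>
    dplyr::group_by(
      .data$experiment_id, .data$participant_id, .data$distractor_shape,
      .data$distractor_texture, .data$total_set_size
    ) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop")
  target_only <- pp[pp$total_set_size == 1, c("participant_id", "rt")]
  names(target_only)[2] <- "rt_target_only"
  distract <- pp[pp$total_set_size > 1, ] |>
    dplyr::left_join(target_only, by = "participant_id")

  distract |>
    dplyr::group_by(
      .data$experiment_id, .data$distractor_shape, .data$distractor_texture,
      .data$participant_id
    ) |>
    dplyr::summarise(
      fit = list(fit_log_efficiency(
        c(1, .data$total_set_size),
        c(.data$rt_target_only[1], .data$rt)
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      D = purrr::map_dbl(.data$fit, "D"),
      RT0 = purrr::map_dbl(.data$fit, "RT0")
    ) |>
    dplyr::group_by(
      .data$experiment_id, .data$distractor_shape, .data$distractor_texture
    ) |>
    dplyr::summarise(
      D = mean(.data$D), RT0 = mean(.data$RT0),
      fit_r2 = NA_real_, cells = list(NULL),
      .groups = "drop"
    )
}
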