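#' Reference single-feature search efficiencies
#'
#' Published group-level estimates for the octagon-target stimulus set that
#' the synthetic generator emulates: logarithmic slopes D (ms per ln-unit of
#' total set size) and mean RTs at total set size 20, for shape-only search
#' (Experiment 1A: shape distractors sharing the cross texture) and
#' texture-only search (Experiment 1B: octagon distractors varying in
#' texture). These values parameterize [study_design()] and serve as inputs
#' to the contrast-combination rules.
#'
#' @return A tibble with columns `experiment_id`, `dimension`,
#'   `distractor_shape`, `distractor_texture`, `D`, `rt_set_size_20`.
#' @export
reference_single_feature <- function() {
  tibble::tribble(
    ~experiment_id, ~dimension, ~distractor_shape, ~distractor_texture, ~D, ~rt_set_size_20,
    "1A", "shape", "house", "cross", 95.2, 846.7,
    "1A", "shape", "square", "cross", 44.9, 693.2,
    "1A", "shape", "triangle", "cross", 46.8, 689.6,
    "1B", "texture", "octagon", "solid", 43.9, 693.2,
    "1B", "texture", "octagon", "tilted_pound", 111.9, 905.8,
    "1B", "texture", "octagon", "dots", 69.5, 766.1
  )
}

#' Reference compound-search efficiencies
#'
#' Published group-level estimates for the two-feature searches in which
#' distractors differ from the octagon-cross target in both shape and
#' texture (Experiments 2A-2C; three shape x texture pairings each).
#'
#' @return A tibble with columns `experiment_id`, `distractor_shape`,
#'   `distractor_texture`, `D`, `rt_set_size_20`.
#' @export
reference_compound <- function() {
  tibble::tribble(
    ~experiment_id, ~distractor_shape, ~distractor_texture, ~D, ~rt_set_size_20,
    "2A", "house", "tilted_pound", 68.6, 756.9,
    "2A", "square", "dots", 28.2, 644.8,
    "2A", "triangle", "solid", 29.1, 638.5,
    "2B", "house", "dots", 49.1, 724.7,
    "2B", "square", "solid", 19.2, 641.6,
    "2B", "triangle", "tilted_pound", 37.0, 687.8,
    "2C", "house", "solid", 38.1, 647.0,
    "2C", "square", "tilted_pound", 46.1, 673.6,
    "2C", "triangle", "dots", 38.7, 657.1
  )
}

# Single-feature D for a shape (from 1A) or texture (from 1B), as named vectors.
reference_shape_D <- function() {
  x <- reference_single_feature()
  x <- x[x$experiment_id == "1A", ]
  setNames(x$D, x$distractor_shape)
}

reference_texture_D <- function() {
  x <- reference_single_feature()
  x <- x[x$experiment_id == "1B", ]
  setNames(x$D, x$distractor_texture)
}

#' Study design and generating parameters for one experiment
#'
#' Returns the condition structure of one of the five reference experiments
#' together with generating parameters whose per-condition true slopes are
#' the reference D estimates. The shared target-only intercept RT0 is
#' back-derived from the reference table as the mean over that experiment's
#' conditions of `rt_set_size_20 - D * ln(20)` (the design has a single
#' target-only condition, so the generative law uses one intercept per
#' experiment).
#'
#' For the compound experiments (2A-2C) the generating slopes can instead be
#' constructed from the single-feature reference slopes under a named
#' combination rule, which is what model-recovery simulations use: data
#' generated under `rule = "orthogonal"` should be won by the orthogonal
#' model, and so on.
#'
#' @param experiment_id One of `"1A"`, `"1B"`, `"2A"`, `"2B"`, `"2C"`.
#' @param rule For experiments 2A-2C, how the generating slopes are chosen:
#'   `"empirical"` (the reference compound estimates, default),
#'   `"best_feature"`, `"orthogonal"`, or `"collinear"` (combine the
#'   single-feature reference slopes under that rule).
#' @param ... Overrides passed to [generating_params()] (noise levels, error
#'   and timeout rates, target sample size, seed).
#' @return A list with elements `design` ([experiment_design()]) and
#'   `params` ([generating_params()]).
#' @export
study_design <- function(experiment_id,
                         rule = c("empirical", "best_feature", "orthogonal", "collinear"),
                         ...) {
  rule <- match.arg(rule)
  experiment_id <- as.character(experiment_id)
  single <- reference_single_feature()
  compound <- reference_compound()

  if (experiment_id %in% c("1A", "1B")) {
    ref <- single[single$experiment_id == experiment_id, ]
  } else if (experiment_id %in% c("2A", "2B", "2C")) {
    ref <- compound[compound$experiment_id == experiment_id, ]
  } else {
    stop("unknown experiment_id: ", experiment_id, call. = FALSE)
  }

  design <- experiment_design(
    experiment_id,
    distractor_conditions = tibble::tibble(
      shape = ref$distractor_shape, texture = ref$distractor_texture
    )
  )

  true_D <- setNames(ref$D, pairing_key(ref$distractor_shape, ref$distractor_texture))
  if (experiment_id %in% c("2A", "2B", "2C") && rule != "empirical") {
    ds <- reference_shape_D()[ref$distractor_shape]
    dt <- reference_texture_D()[ref$distractor_texture]
    true_D[] <- switch(rule,
      best_feature = combine_best(ds, dt),
      orthogonal = combine_orthogonal(ds, dt),
      collinear = combine_collinear(ds, dt)
    )
  }
  # intercept is a property of the observer group, not of the combination rule
  rt0_mean <- mean(ref$rt_set_size_20 - ref$D * log(20))

  params <- generating_params(true_D = true_D, true_RT0_mean = rt0_mean, ...)
  list(design = design, params = params)
}
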