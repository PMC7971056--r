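#' Configuration for the full estimate-then-predict pipeline
#'
#' @param experiments Experiment ids to run. Any compound experiment
#'   (2A/2B/2C) requires both single-feature experiments 1A and 1B, whose
#'   fitted slopes feed the combination rules.
#' @param seed Master seed; each experiment derives its own generator seed
#'   from it by counter.
#' @param accuracy_min,rt_sd_k Screening thresholds.
#' @param models Combination models to evaluate.
#' @param rt0_source Intercept used when predicting compound-search RTs:
#'   each experiment's own observed target-only mean (`"per_experiment"`,
#'   default) or the mean over the compound experiments (`"pooled"`).
#' @param exp2_rule Generating rule for the compound cohorts (see
#'   [study_design()]); `"empirical"` reproduces the reference estimates,
#'   the rule names drive model-recovery simulations.
#' @param outdir Directory for stage artifacts (trials, summaries,
#'   efficiencies, predictions, report.json, figure); `NULL` writes nothing.
#' @param params Named list of [generating_params()] overrides applied to
#'   every experiment (e.g. `trial_noise_sd`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(experiments = c("1A", "1B", "2A", "2B", "2C"),
                            seed = 1L,
                            accuracy_min = 0.90, rt_sd_k = 2.0,
                            models = c("best_feature", "orthogonal", "collinear", "reciprocal"),
                            rt0_source = c("per_experiment", "pooled"),
                            exp2_rule = "empirical",
                            outdir = NULL,
                            params = list()) {
  rt0_source <- match.arg(rt0_source)
  experiments <- as.character(experiments)
  unknown <- setdiff(experiments, c("1A", "1B", "2A", "2B", "2C"))
  if (length(unknown) > 0) stop("unknown experiment(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  exp2 <- intersect(experiments, c("2A", "2B", "2C"))
  if (length(exp2) > 0 && !all(c("1A", "1B") %in% experiments)) {
    stop("compound experiments (", paste(exp2, collapse = ", "),
      ") require both 1A and 1B in the run",
      call. = FALSE
    )
  }
  structure(
    list(
      experiments = experiments, seed = as.integer(seed),
      accuracy_min = accuracy_min, rt_sd_k = rt_sd_k,
      models = models, rt0_source = rt0_source,
      exp2_rule = exp2_rule, outdir = outdir, params = params
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full estimate-then-predict pipeline
#'
#' Simulates each configured experiment's cohort, screens participants
#' (accuracy then RT-outlier rules), keeps correct non-timeout trials from
#' included participants, fits the logarithmic efficiency law per condition,
#' predicts the compound-search RTs from the single-feature fits under each
#' combination model (plus the reciprocal-of-RT regression at set size 20),
#' and compares the models. Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param quiet Suppress per-stage log lines?
#' @return A `pipeline_result` list: `report`
#'   ([compare_models()] output), `efficiencies`, `predictions` (named list
#'   of prediction sets), `cell_means`, `screening`, `truth`, `config`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  cohorts <- list()
  truths <- list()
  screening <- list()
  filtered <- list()
  for (i in seq_along(config$experiments)) {
    ex <- config$experiments[i]
    rule <- if (ex %in% c("2A", "2B", "2C")) config$exp2_rule else "empirical"
    sd_args <- c(
      list(experiment_id = ex, rule = rule, seed = config$seed + i),
      config$params
    )
    setup <- do.call(study_design, sd_args)
    sim <- simulate_experiment(setup$design, setup$params,
      accuracy_min = config$accuracy_min, rt_sd_k = config$rt_sd_k
    )
    # post-hoc screening over the full generated cohort, via the screening module
    summaries <- summarize_participants(sim$trials)
    screened <- apply_exclusions(summaries,
      accuracy_min = config$accuracy_min, rt_sd_k = config$rt_sd_k
    )
    filt <- filter_trials(sim$trials, screened)
    pipeline_log(
      quiet,
      "[%s] simulated %d candidates (%d trials); included %d (excluded: %s); %d analyzable trials",
      ex, nrow(screened), nrow(sim$trials), sum(screened$included),
      paste(names(table(screened$exclusion_reason[!screened$included])),
        table(screened$exclusion_reason[!screened$included]),
        sep = "=", collapse = ", "
      ),
      nrow(filt)
    )
    cohorts[[ex]] <- sim$trials
    truths[[ex]] <- sim$truth
    screening[[ex]] <- screened
    filtered[[ex]] <- filt
    if (!is.null(outdir)) {
      write_trials(sim$trials, file.path(outdir, sprintf("trials_%s.csv", ex)))
      readr::write_csv(screened, file.path(outdir, sprintf("screening_%s.csv", ex)))
    }
  }

  cells <- purrr::map(filtered, aggregate_condition_means)
  eff <- purrr::map(cells, fit_experiment_efficiencies)
  efficiencies <- dplyr::bind_rows(eff)
  pipeline_log(
    quiet, "fitted %d condition efficiencies across %d experiment(s)",
    nrow(efficiencies), length(eff)
  )
  if (!is.null(outdir)) {
    readr::write_csv(
      efficiencies |> dplyr::select(-"cells"),
      file.path(outdir, "efficiencies.csv")
    )
  }

  exp2 <- intersect(config$experiments, c("2A", "2B", "2C"))
  if (length(exp2) == 0) {
    return(structure(
      list(
        report = NULL, efficiencies = efficiencies, predictions = NULL,
        cell_means = cells, screening = screening, truth = truths,
        config = config
      ),
      class = "pipeline_result"
    ))
  }

  shape_D <- setNames(eff[["1A"]]$D, eff[["1A"]]$distractor_shape)
  texture_D <- setNames(eff[["1B"]]$D, eff[["1B"]]$distractor_texture)

  obs2 <- dplyr::bind_rows(cells[exp2])
  target_only2 <- obs2 |> dplyr::filter(.data$total_set_size == 1)
  rt0_by_exp <- setNames(target_only2$mean_rt_ms, target_only2$experiment_id)
  if (config$rt0_source == "pooled") {
    rt0_by_exp[] <- mean(rt0_by_exp)
  }
  obs2 <- obs2 |> dplyr::filter(.data$total_set_size > 1)

  slope_models <- intersect(config$models, names(combination_rules()))
  predictions <- list()
  for (m in slope_models) {
    comb <- combine_efficiencies(
      obs2 |> dplyr::distinct(.data$distractor_shape, .data$distractor_texture),
      shape_D, texture_D,
      models = m
    )
    tab <- obs2 |>
      dplyr::left_join(
        comb |> dplyr::select("distractor_shape", "distractor_texture", "D_overall"),
        by = c("distractor_shape", "distractor_texture")
      ) |>
      dplyr::mutate(rt_predicted = predict_rt(
        rt0_by_exp[.data$experiment_id], .data$D_overall, .data$total_set_size
      ))
    predictions[[m]] <- prediction_set(
      m,
      condition = pairing_key(tab$distractor_shape, tab$distractor_texture),
      total_set_size = tab$total_set_size,
      rt_predicted = tab$rt_predicted,
      rt_observed = tab$mean_rt_ms,
      se_observed = tab$se_rt_ms,
      n_free_params = 0L
    )
  }

  obs20_n <- sum(obs2$total_set_size == 20L)
  if ("reciprocal" %in% config$models && obs20_n < 4L) {
    pipeline_log(
      quiet,
      "skipping the reciprocal-of-RT model: only %d set-size-20 points (need >= 4)",
      obs20_n
    )
  }
  if ("reciprocal" %in% config$models && obs20_n >= 4L) {
    ss_fix <- 20L
    cells1A <- eff[["1A"]] |>
      dplyr::mutate(rt_fix = purrr::map_dbl(
        .data$cells, ~ .x$mean_rt_ms[.x$total_set_size == ss_fix]
      ))
    cells1B <- eff[["1B"]] |>
      dplyr::mutate(rt_fix = purrr::map_dbl(
        .data$cells, ~ .x$mean_rt_ms[.x$total_set_size == ss_fix]
      ))
    rt_shape_by <- setNames(cells1A$rt_fix, cells1A$distractor_shape)
    rt_texture_by <- setNames(cells1B$rt_fix, cells1B$distractor_texture)
    obs20 <- obs2 |> dplyr::filter(.data$total_set_size == ss_fix)
    rs <- rt_shape_by[obs20$distractor_shape]
    rtex <- rt_texture_by[obs20$distractor_texture]
    rfit <- fit_reciprocal(rs, rtex, obs20$mean_rt_ms, fixed_set_size = ss_fix)
    predictions[["reciprocal"]] <- prediction_set(
      "reciprocal",
      condition = pairing_key(obs20$distractor_shape, obs20$distractor_texture),
      total_set_size = obs20$total_set_size,
      rt_predicted = predict_reciprocal(rfit, rs, rtex),
      rt_observed = obs20$mean_rt_ms,
      se_observed = obs20$se_rt_ms,
      n_free_params = 3L
    )
  }

  report <- compare_models(predictions,
    restricted = intersect("reciprocal", names(predictions))
  )
  pipeline_log(
    quiet, "compared %d model(s) on %d points; AIC winner: %s",
    length(predictions), report$models$n[1], report$winner
  )

  if (!is.null(outdir)) {
    pred_tab <- purrr::imap_dfr(predictions, function(p, m) {
      tibble::as_tibble(p) |> dplyr::mutate(model = m, .before = 1)
    })
    readr::write_csv(pred_tab, file.path(outdir, "predictions.csv"))
    jsonlite::write_json(
      report_to_list(report),
      file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    fig <- plot_observed_vs_predicted(predictions)
    ggplot2::ggsave(file.path(outdir, "observed_vs_predicted.png"), fig,
      width = 9, height = 3.2, dpi = 150
    )
  }

  structure(
    list(
      report = report, efficiencies = efficiencies, predictions = predictions,
      cell_means = cells, screening = screening, truth = truths,
      config = config
    ),
    class = "pipeline_result"
  )
}

# Plain-list view of a comparison report for JSON serialization.
report_to_list <- function(report) {
  list(
    models = purrr::set_names(
      purrr::map(seq_len(nrow(report$models)), function(i) {
        r <- report$models[i, ]
        list(
          r2 = r$r2, rss = r$rss, aic = r$aic,
          rel_likelihood = r$rel_likelihood,
          evidence_ratio = r$evidence_ratio,
          evidence_ratio_rounded = round(r$evidence_ratio),
          mae_ms = r$mae_ms, n = r$n
        )
      }),
      report$models$model
    ),
    winner = report$winner,
    pairwise_tests = if (is.null(report$pairwise)) list() else report$pairwise,
    coverage = report$coverage,
    restricted = purrr::map(report$restricted, function(rb) {
      list(points = rb$points, models = rb$models)
    }),
    bayes_factors = "not implemented"
  )
}

#' Observed versus predicted RT scatter
#'
#' One panel per model: observed group-mean RTs against model predictions,
#' with the identity line and the least-squares slope through the cloud.
#'
#' @param predictions Named list of [prediction_set()] objects.
#' @return A ggplot object.
#' @export
plot_observed_vs_predicted <- function(predictions) {
  tab <- purrr::imap_dfr(predictions, function(p, m) {
    tibble::as_tibble(p) |> dplyr::mutate(model = m)
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rt_predicted, y = .data$rt_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$rt_observed - 1.96 * .data$se_observed,
        ymax = .data$rt_observed + 1.96 * .data$se_observed
      ),
      width = 0, colour = "grey40", na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Predicted RT (ms)", y = "Observed RT (ms)") +
    ggplot2::theme_minimal()
}

#' Combination-rule comparison on the reference efficiency tables
#'
#' Skips simulation entirely: combines the single-feature reference slopes
#' under each rule and scores the combined slopes against the observed
#' compound-search slopes by mean absolute deviation (ms per ln-unit).
#'
#' @return A list: `table` (per pairing x model: predicted and observed
#'   `D_overall`), `mad` (named vector of mean absolute deviations), and
#'   `winner` (rule with the smallest deviation).
#' @export
demo_fixture_comparison <- function() {
  obs <- reference_compound()
  comb <- combine_efficiencies(
    obs, reference_shape_D(), reference_texture_D()
  ) |>
    dplyr::rename(D_observed = "D", D_predicted = "D_overall")
  mad <- comb |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mad = mean(abs(.data$D_predicted - .data$D_observed))) |>
    (\(x) setNames(x$mad, x$model))()
  list(table = comb, mad = mad, winner = names(which.min(mad)))
}
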