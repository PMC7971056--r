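#' Bundle aligned predictions and observations for one model
#'
#' @param model Model name.
#' @param condition Condition labels.
#' @param total_set_size Total set sizes.
#' @param rt_predicted,rt_observed Aligned predicted and observed RTs, ms.
#' @param se_observed Standard errors of the observed means, ms (`NA`
#'   allowed; required only for coverage).
#' @param n_free_params Free parameters the model spent on these predictions
#'   (0 for the slope-combination rules, 3 for the reciprocal-of-RT fit).
#' @return A `prediction_set` tibble.
#' @export
prediction_set <- function(model, condition, total_set_size,
                           rt_predicted, rt_observed,
                           se_observed = NA_real_, n_free_params = 0L) {
  out <- tibble::tibble(
    condition = condition,
    total_set_size = as.integer(total_set_size),
    rt_predicted = rt_predicted,
    rt_observed = rt_observed,
    se_observed = se_observed
  )
  if (nrow(out) == 0) stop("empty prediction set", call. = FALSE)
  if (any(!is.na(out$se_observed) & out$se_observed < 0)) {
    stop("negative observed SE", call. = FALSE)
  }
  structure(out,
    model = as.character(model),
    n_free_params = as.integer(n_free_params),
    class = c("prediction_set", class(out))
  )
}

ps_model <- function(x) attr(x, "model")
ps_k <- function(x) attr(x, "n_free_params")

#' Coefficient of determination of a prediction set
#'
#' Default is one minus the ratio of the residual to the total sum of
#' squares, `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`; it can be
#' negative for predictions worse than the observed mean. The alternative is
#' the squared Pearson correlation of predicted and observed values.
#'
#' @param pred A [prediction_set()] with at least 2 points.
#' @param method `"rss"` (default) or `"correlation"`.
#' @return R-squared as a proportion.
#' @export
r_squared <- function(pred, method = c("rss", "correlation")) {
  method <- match.arg(method)
  obs <- pred$rt_observed
  if (length(obs) < 2) stop("r_squared needs at least 2 points", call. = FALSE)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) stop("observed values are constant; R^2 undefined", call. = FALSE)
  if (method == "correlation") {
    return(stats::cor(pred$rt_predicted, obs)^2)
  }
  1 - sum((obs - pred$rt_predicted)^2) / tss
}

#' Gaussian AIC of a prediction set
#'
#' Full Gaussian log-likelihood convention with the residual variance counted
#' as a fitted parameter:
#' `AIC = n*ln(2*pi) + n*ln(RSS/n) + n + 2*k`, with `k = n_free_params + 1`.
#' Only AIC differences matter for relative likelihoods, and for models with
#' equal `k` those differences are invariant to the constant convention.
#'
#' @param pred A [prediction_set()] with at least 2 points.
#' @return The AIC value; `-Inf` (with a warning) for a perfect fit.
#' @export
gaussian_aic <- function(pred) {
  n <- nrow(pred)
  if (n < 2) stop("gaussian_aic needs at least 2 points", call. = FALSE)
  rss <- sum((pred$rt_observed - pred$rt_predicted)^2)
  k <- ps_k(pred) + 1L
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(2 * pi) + n * log(rss / n) + n + 2 * k
}

#' AIC relative likelihoods
#'
#' For each model, `exp((AIC_min - AIC_i) / 2)`: the probability that model i
#' minimizes information loss relative to the best model. The AIC winner gets
#' exactly 1; the familiar "x times more likely" evidence factor of the
#' winner over model i is the reciprocal, returned alongside.
#'
#' @param aics Named numeric vector of AIC values (>= 2 models).
#' @return A tibble with `model`, `aic`, `rel_likelihood`, `evidence_ratio`
#'   (winner over this model), sorted by AIC.
#' @export
relative_likelihoods <- function(aics) {
  if (length(aics) < 2 || is.null(names(aics))) {
    stop("relative_likelihoods needs a named vector of >= 2 AICs", call. = FALSE)
  }
  rl <- exp((min(aics) - aics) / 2)
  tibble::tibble(
    model = names(aics),
    aic = unname(aics),
    rel_likelihood = unname(rl),
    evidence_ratio = unname(1 / rl)
  ) |>
    dplyr::arrange(.data$aic)
}

#' Mean absolute prediction error
#'
#' @param pred A [prediction_set()].
#' @return Mean of `|observed - predicted|`, ms.
#' @export
mean_abs_prediction_error <- function(pred) {
  mean(abs(pred$rt_observed - pred$rt_predicted))
}

#' Paired t test on per-point absolute prediction errors
#'
#' Compares two models' absolute errors on the same observation points with
#' a paired t test computed in closed form: for differences `d`,
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`, two-tailed p, and the
#' paired-samples effect size `dz = mean(d) / sd(d)`.
#'
#' @param errors_a,errors_b Aligned absolute errors of the two models.
#' @return A list: `t`, `df`, `p`, `dz`, `mean_diff`.
#' @export
paired_error_test <- function(errors_a, errors_b) {
  n <- length(errors_a)
  stopifnot(length(errors_b) == n)
  if (n < 2) stop("paired test needs at least 2 points", call. = FALSE)
  d <- errors_a - errors_b
  s <- sd(d)
  if (s == 0) {
    stop("zero variance of error differences; paired t undefined", call. = FALSE)
  }
  tval <- mean(d) / (s / sqrt(n))
  list(
    t = tval,
    df = n - 1L,
    p = 2 * pt(-abs(tval), df = n - 1L),
    dz = mean(d) / s,
    mean_diff = mean(d)
  )
}

#' Margin-of-error coverage of predictions
#'
#' Counts predictions falling inside the observed mean plus or minus
#' `z` times its standard error, boundary inclusive.
#'
#' @param pred A [prediction_set()] with non-missing `se_observed`.
#' @param z Half-width of the interval in SE units (1.96 for a 95% margin).
#' @return A list: `covered`, `total`.
#' @export
moe_coverage <- function(pred, z = 1.96) {
  if (any(is.na(pred$se_observed))) {
    stop("coverage needs a standard error for every observation", call. = FALSE)
  }
  half_width <- z * pred$se_observed
  # boundary-inclusive up to floating-point rounding of the margin
  tol <- 1e-8 * pmax(half_width, 1)
  covered <- abs(pred$rt_predicted - pred$rt_observed) <= half_width + tol
  list(covered = sum(covered), total = nrow(pred))
}

#' Score and compare competing prediction models
#'
#' Scores every model on R-squared, RSS, Gaussian AIC, AIC relative
#' likelihood, mean absolute prediction error and margin-of-error coverage;
#' runs paired t tests of per-point absolute errors between the AIC winner
#' and each rival; and, when some models (here the reciprocal-of-RT model)
#' predict only a restricted observation subset, re-scores the main winner
#' against them head-to-head on exactly that subset.
#'
#' @param predictions Named list of [prediction_set()] objects. Models named
#'   in `restricted` may cover a subset of the observation points; all others
#'   must be aligned on identical (condition, set size) points.
#' @param restricted Character vector of model names evaluated only on their
#'   own (restricted) points; default auto-detects sets whose points are a
#'   proper subset of the main alignment.
#' @param z Margin-of-error width in SE units.
#' @return A `model_comparison_report`: `models` tibble, `pairwise` tibble,
#'   `coverage` tibble, `winner`, and `restricted` (head-to-head block or
#'   `NULL`). Bayes factors are intentionally absent from the schema.
#' @export
compare_models <- function(predictions, restricted = NULL, z = 1.96) {
  stopifnot(is.list(predictions), length(predictions) >= 1)
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    names(predictions) <- vapply(predictions, ps_model, character(1))
  }
  keys <- lapply(predictions, function(p) paste(p$condition, p$total_set_size))
  if (is.null(restricted)) {
    main_key <- keys[[which.max(lengths(keys))]]
    restricted <- names(predictions)[vapply(
      keys, function(k) length(k) < length(main_key) && all(k %in% main_key), logical(1)
    )]
  }
  main <- setdiff(names(predictions), restricted)
  if (length(main) == 0) stop("no models left on the common point set", call. = FALSE)
  ref_key <- sort(keys[[main[1]]])
  for (m in main) {
    if (!identical(sort(keys[[m]]), ref_key)) {
      stop("prediction sets are misaligned: model '", m,
        "' covers different observation points",
        call. = FALSE
      )
    }
  }

  score_one <- function(p) {
    tibble::tibble(
      model = ps_model(p),
      n = nrow(p),
      n_free_params = ps_k(p),
      r2 = r_squared(p),
      rss = sum((p$rt_observed - p$rt_predicted)^2),
      aic = gaussian_aic(p),
      mae_ms = mean_abs_prediction_error(p)
    )
  }
  models <- purrr::map_dfr(predictions[main], score_one)
  if (nrow(models) > 1) {
    rl <- relative_likelihoods(setNames(models$aic, models$model))
    models <- dplyr::left_join(
      models, rl[, c("model", "rel_likelihood", "evidence_ratio")],
      by = "model"
    ) |>
      dplyr::arrange(.data$aic)
  } else {
    models$rel_likelihood <- 1
    models$evidence_ratio <- 1
  }
  winner <- models$model[1]

  pairwise <- NULL
  if (length(main) > 1) {
    ord <- function(p) order(paste(p$condition, p$total_set_size))
    pw <- predictions[[winner]]
    ew <- abs(pw$rt_observed - pw$rt_predicted)[ord(pw)]
    pairwise <- purrr::map_dfr(setdiff(main, winner), function(m) {
      pm <- predictions[[m]]
      em <- abs(pm$rt_observed - pm$rt_predicted)[ord(pm)]
      tt <- tryCatch(paired_error_test(em, ew), error = function(e) NULL)
      tibble::tibble(
        model_a = winner, model_b = m,
        t = if (is.null(tt)) NA_real_ else tt$t,
        df = if (is.null(tt)) NA_integer_ else tt$df,
        p = if (is.null(tt)) NA_real_ else tt$p,
        dz = if (is.null(tt)) NA_real_ else tt$dz
      )
    })
  }

  coverage <- purrr::map_dfr(predictions[main], function(p) {
    cv <- tryCatch(moe_coverage(p, z = z), error = function(e) NULL)
    tibble::tibble(
      model = ps_model(p),
      covered = if (is.null(cv)) NA_integer_ else cv$covered,
      total = if (is.null(cv)) NA_integer_ else cv$total
    )
  })

  restricted_block <- NULL
  if (length(restricted) > 0) {
    restricted_block <- purrr::map(setNames(restricted, restricted), function(m) {
      pr <- predictions[[m]]
      rkey <- paste(pr$condition, pr$total_set_size)
      pw_full <- predictions[[winner]]
      keep <- paste(pw_full$condition, pw_full$total_set_size) %in% rkey
      if (!any(keep)) {
        stop("restricted model '", m, "' shares no points with the winner", call. = FALSE)
      }
      pw <- prediction_set(
        winner, pw_full$condition[keep], pw_full$total_set_size[keep],
        pw_full$rt_predicted[keep], pw_full$rt_observed[keep],
        pw_full$se_observed[keep], ps_k(pw_full)
      )
      both <- purrr::map_dfr(list(pw, pr), score_one)
      rl2 <- relative_likelihoods(setNames(both$aic, both$model))
      list(
        models = dplyr::left_join(
          both, rl2[, c("model", "rel_likelihood", "evidence_ratio")],
          by = "model"
        ) |> dplyr::arrange(.data$aic),
        points = sum(keep)
      )
    })
  }

  structure(
    list(
      models = models, pairwise = pairwise, coverage = coverage,
      winner = winner, restricted = restricted_block, z = z
    ),
    class = "model_comparison_report"
  )
}

#' @export
print.model_comparison_report <- function(x, ...) {
  cat("Model comparison (", nrow(x$models), " models on ",
    x$models$n[1], " points)\n",
    sep = ""
  )
  df <- as.data.frame(x$models)
  df$r2 <- sprintf("%.2f%%", 100 * df$r2)
  df$mae_ms <- sprintf("%.2f", df$mae_ms)
  df$aic <- sprintf("%.2f", df$aic)
  df$evidence_ratio <- sprintf("%.1f", df$evidence_ratio)
  print(df[, c("model", "r2", "aic", "rel_likelihood", "evidence_ratio", "mae_ms")],
    row.names = FALSE
  )
  cat("AIC winner:", x$winner, "\n")
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      pw <- x$pairwise[i, ]
      cat(sprintf(
        "  |err| %s vs %s: t(%d) = %.2f, p = %.3g, dz = %.3f\n",
        pw$model_b, pw$model_a, pw$df, pw$t, pw$p, pw$dz
      ))
    }
  }
  cv <- x$coverage[x$coverage$model == x$winner, ]
  if (nrow(cv) == 1 && !is.na(cv$covered)) {
    cat(sprintf(
      "  coverage (winner, +/- %.2f SE): %d of %d predictions\n",
      x$z, cv$covered, cv$total
    ))
  }
  for (m in names(x$restricted)) {
    rb <- x$restricted[[m]]
    cat(sprintf(
      "  restricted head-to-head on %d points: %s\n", rb$points,
      paste(sprintf(
        "%s AIC = %.2f (rel. lik. %.3g)",
        rb$models$model, rb$models$aic, rb$models$rel_likelihood
      ), collapse = "; ")
    ))
  }
  invisible(x)
}
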