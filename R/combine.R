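#' Target-distractor contrast from a search-efficiency slope
#'
#' Under Target Contrast Signal theory the distinctiveness (contrast) of a
#' distractor from the target is inversely proportional to the logarithmic
#' search slope: `contrast = alpha / D`. The proportionality constant cancels
#' whenever contrasts are combined and mapped back to slopes, so it is fixed
#' at 1 and kept only to document that cancellation.
#'
#' @param D Search-efficiency slope(s), ms per ln-unit; must be positive.
#' @param alpha Multiplicative constant (dimension carrier), default 1.
#' @return Dimensionless contrast value(s).
#' @export
contrast_from_slope <- function(D, alpha = 1) {
  check_positive_D(D)
  alpha / D
}

check_positive_D <- function(..., what = "efficiency slope") {
  vals <- c(...)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop(what, " must be positive and finite", call. = FALSE)
  }
  invisible(vals)
}

#' Combine single-feature efficiencies: best-feature guidance
#'
#' Guidance relies only on the feature dimension with the larger contrast,
#' i.e. the smaller slope; the other dimension is ignored:
#' `D_overall = min(D_shape, D_texture)`.
#'
#' @param D_shape,D_texture Single-feature slopes, ms per ln-unit; positive.
#'   Vectorized and symmetric in their arguments.
#' @return Combined slope(s) `D_overall`.
#' @export
combine_best <- function(D_shape, D_texture) {
  check_positive_D(D_shape, D_texture)
  pmin(D_shape, D_texture)
}

#' Combine single-feature efficiencies: orthogonal (Euclidean) combination
#'
#' Contrasts live in a shared space and add as orthogonal components
#' (`overall^2 = shape^2 + texture^2`, the Euclidean metric — the signature
#' of integral feature dimensions). In slope terms:
#' `D_overall = 1 / sqrt((1/D_shape)^2 + (1/D_texture)^2)`.
#'
#' @inheritParams combine_best
#' @return Combined slope(s) `D_overall`.
#' @export
combine_orthogonal <- function(D_shape, D_texture) {
  check_positive_D(D_shape, D_texture)
  1 / sqrt((1 / D_shape)^2 + (1 / D_texture)^2)
}

#' Combine single-feature efficiencies: collinear (city-block) integration
#'
#' Contrasts are kept in separate dimensions and summed linearly
#' (`overall = shape + texture`, the city-block metric — the signature of
#' separable feature dimensions). In slope terms this is the harmonic
#' composition `D_overall = D_shape * D_texture / (D_shape + D_texture)`,
#' equivalently `1/D_overall = 1/D_shape + 1/D_texture`.
#'
#' @inheritParams combine_best
#' @return Combined slope(s) `D_overall`.
#' @export
combine_collinear <- function(D_shape, D_texture) {
  check_positive_D(D_shape, D_texture)
  (D_shape * D_texture) / (D_shape + D_texture)
}

# Dispatch table shared by the tidy wrapper and the pipeline.
combination_rules <- function() {
  list(
    best_feature = combine_best,
    orthogonal = combine_orthogonal,
    collinear = combine_collinear
  )
}

#' Combined efficiencies for a set of shape x texture pairings
#'
#' Tidy wrapper over the three combination rules: looks up each pairing's
#' single-feature slopes and returns one row per pairing x model.
#'
#' @param pairings Data frame with `distractor_shape`, `distractor_texture`
#'   (and optionally other columns, which are carried through).
#' @param shape_D,texture_D Named numeric vectors of single-feature slopes,
#'   indexed by shape resp. texture.
#' @param models Character subset of
#'   `c("best_feature", "orthogonal", "collinear")`.
#' @return A tibble with `model`, `D_shape`, `D_texture`, `D_overall`
#'   appended to the pairing columns.
#' @export
combine_efficiencies <- function(pairings, shape_D, texture_D,
                                 models = names(combination_rules())) {
  rules <- combination_rules()
  models <- match.arg(models, names(rules), several.ok = TRUE)
  pairings <- tibble::as_tibble(pairings)
  miss_s <- setdiff(pairings$distractor_shape, names(shape_D))
  miss_t <- setdiff(pairings$distractor_texture, names(texture_D))
  if (length(miss_s) || length(miss_t)) {
    stop(
      "no single-feature slope for: ",
      paste(c(miss_s, miss_t), collapse = ", "),
      call. = FALSE
    )
  }
  purrr::map_dfr(models, function(m) {
    pairings |>
      dplyr::mutate(
        model = m,
        D_shape = unname(shape_D[.data$distractor_shape]),
        D_texture = unname(texture_D[.data$distractor_texture]),
        D_overall = rules[[m]](.data$D_shape, .data$D_texture)
      )
  })
}

#' Predict search RT from the logarithmic efficiency law
#'
#' `RT = RT0 + D_overall * ln(total_set_size)`, where RT0 is the target-only
#' response time and the total set size counts all distractors plus the
#' target.
#'
#' @param RT0 Target-only response time, ms.
#' @param D_overall Efficiency slope, ms per ln-unit.
#' @param total_set_size Total set size(s), >= 1.
#' @return Predicted RT(s), ms.
#' @export
predict_rt <- function(RT0, D_overall, total_set_size) {
  if (any(total_set_size < 1)) {
    stop("total_set_size must be >= 1", call. = FALSE)
  }
  RT0 + D_overall * log(total_set_size)
}

#' Fit the reciprocal-of-RT combination model
#'
#' Uses 1/RT at one fixed set size (20 here) as the distinctiveness index
#' instead of the slope, and regresses the compound-search reciprocal on the
#' two single-feature reciprocals:
#' `1/RT_both = a * (1/RT_shape) + b * (1/RT_texture) + c`,
#' with `a`, `b`, `c` free parameters minimizing squared residual error in
#' 1/RT space.
#'
#' @param rt_shape,rt_texture,rt_both Aligned RTs (ms) at the fixed set size
#'   for shape-only, texture-only and compound search; at least 4 points
#'   (9 in the reference design).
#' @param fixed_set_size The set size the RTs were measured at (metadata).
#' @return A `reciprocal_fit` list: `a`, `b`, `c`, `rss` (in 1/RT space),
#'   `fixed_set_size`, `n`.
#' @export
fit_reciprocal <- function(rt_shape, rt_texture, rt_both, fixed_set_size = 20L) {
  n <- length(rt_both)
  stopifnot(length(rt_shape) == n, length(rt_texture) == n)
  if (n < 4) stop("fit_reciprocal needs at least 4 observations", call. = FALSE)
  check_positive_D(rt_shape, rt_texture, rt_both, what = "RT")
  x1 <- 1 / rt_shape
  x2 <- 1 / rt_texture
  y <- 1 / rt_both
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) {
    stop("collinearity: reciprocal predictors (with intercept) are rank-deficient",
      call. = FALSE
    )
  }
  fit <- lm(y ~ x1 + x2)
  structure(
    list(
      a = unname(coef(fit)["x1"]),
      b = unname(coef(fit)["x2"]),
      c = unname(coef(fit)["(Intercept)"]),
      rss = sum(fit$residuals^2),
      fixed_set_size = as.integer(fixed_set_size),
      n = n
    ),
    class = "reciprocal_fit"
  )
}

#' Predict compound-search RT from a reciprocal-of-RT fit
#'
#' Evaluates `1/RT = a/rt_shape + b/rt_texture + c` and returns the
#' prediction back in RT space (ms). A non-positive predicted reciprocal has
#' no RT-space counterpart and raises an error naming the offending points.
#'
#' @param fit A [fit_reciprocal()] object.
#' @param rt_shape,rt_texture Single-feature RTs (ms) at the fit's fixed set
#'   size.
#' @return Predicted compound-search RT(s), ms.
#' @export
predict_reciprocal <- function(fit, rt_shape, rt_texture) {
  stopifnot(inherits(fit, "reciprocal_fit"))
  check_positive_D(rt_shape, rt_texture, what = "RT")
  recip <- fit$a / rt_shape + fit$b / rt_texture + fit$c
  bad <- which(recip <= 0)
  if (length(bad)) {
    stop(
      "non-positive predicted reciprocal RT at point(s) ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  1 / recip
}

#' @export
print.reciprocal_fit <- function(x, ...) {
  cat(sprintf(
    "Reciprocal-of-RT fit (set size %d, n = %d): 1/RT = %.4g/RT_shape + %.4g/RT_texture + %.4g (RSS = %.3g in 1/RT space)\n",
    x$fixed_set_size, x$n, x$a, x$b, x$c, x$rss
  ))
  invisible(x)
}
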