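ps <- function(pred, obs, se = NA_real_, k = 0L, model = "m",
               ss = rep(20L, length(obs))) {
  prediction_set(model, sprintf("c%02d", seq_along(obs)), ss, pred, obs, se, k)
}

test_that("R-squared follows the residual-sum-of-squares definition", {
  obs <- c(600, 650, 700, 750)
  expect_equal(r_squared(ps(obs, obs)), 1)
  expect_equal(r_squared(ps(rep(mean(obs), 4), obs)), 0)
  expect_equal(r_squared(ps(c(610, 690), c(600, 700))), 1 - 200 / 5000) # 0.96
  expect_error(r_squared(ps(c(600, 610), c(700, 700))), "constant")
  # the squared-correlation alternative is insensitive to offset
  shifted <- ps(obs + 50, obs)
  expect_equal(r_squared(shifted, method = "correlation"), 1)
  expect_lt(r_squared(shifted), 1)
})

test_that("the Gaussian AIC matches its closed form and algebraic identities", {
  resid9 <- rep(c(1, -1), length.out = 9) # RSS = 9
  obs <- 600 + cumsum(rep(5, 9))
  a1 <- gaussian_aic(ps(obs + resid9, obs, k = 0L))
  expect_equal(a1, 9 * log(2 * pi) + 9 * log(1) + 9 + 2, tolerance = 1e-12) # ~27.54

  # doubling the RSS raises AIC by n*ln(2)
  a2 <- gaussian_aic(ps(obs + sqrt(2) * resid9, obs, k = 0L))
  expect_equal(a2 - a1, 9 * log(2), tolerance = 1e-10)

  # extra free parameters cost 2 each at fixed RSS
  a3 <- gaussian_aic(ps(obs + resid9, obs, k = 3L))
  expect_equal(a3 - a1, 6)

  expect_warning(perfect <- gaussian_aic(ps(obs, obs)), "zero residual")
  expect_identical(perfect, -Inf)
})

test_that("AIC relative likelihoods reproduce the published evidence ratios", {
  rl <- relative_likelihoods(
    c(orthogonal = 288.45, best_feature = 297.10, collinear = 296.39)
  )
  expect_identical(rl$model[1], "orthogonal")
  expect_equal(rl$rel_likelihood[1], 1)
  er <- setNames(rl$evidence_ratio, rl$model)
  expect_equal(er[["best_feature"]], exp((297.10 - 288.45) / 2), tolerance = 1e-12)
  expect_equal(er[["best_feature"]], 75.566, tolerance = 1e-4)
  expect_equal(er[["collinear"]], 52.985, tolerance = 1e-4)

  rl20 <- relative_likelihoods(c(orthogonal = 76.25, reciprocal = 80.41))
  expect_equal(rl20$evidence_ratio[2], 8.004, tolerance = 1e-3)

  tie <- relative_likelihoods(c(a = 100, b = 100))
  expect_equal(tie$rel_likelihood, c(1, 1))
})

test_that("mean absolute prediction error averages unsigned errors", {
  obs <- c(600, 650, 700, 750)
  expect_equal(mean_abs_prediction_error(ps(obs, obs)), 0)
  expect_equal(mean_abs_prediction_error(ps(obs + c(10, -10, 10, -10), obs)), 10)
  expect_equal(mean_abs_prediction_error(ps(obs + c(5, 15, 25, 15), obs)), 15)
})

test_that("the paired error test matches stats::t.test", {
  set.seed(77)
  ea <- abs(rnorm(36, 20, 8))
  eb <- abs(rnorm(36, 14, 8))
  ours <- paired_error_test(ea, eb)
  ref <- t.test(ea, eb, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_identical(ours$df, 35L)
  expect_equal(ours$dz, mean(ea - eb) / sd(ea - eb), tolerance = 1e-12)

  d <- c(1, 1, 1, 1.1)
  small <- paired_error_test(2 + d, rep(2, 4))
  expect_equal(small$t, unname(t.test(2 + d - 2)$statistic), tolerance = 1e-12)

  expect_error(paired_error_test(ea, ea), "zero variance")
})

test_that("margin-of-error coverage is boundary-inclusive and monotone in z", {
  obs <- seq(600, 750, length.out = 36)
  se <- rep(10, 36)
  exact <- moe_coverage(ps(obs, obs, se))
  expect_identical(exact$covered, 36L)
  expect_identical(exact$total, 36L)

  at_boundary <- moe_coverage(ps(obs + 1.96 * se, obs, se))
  expect_identical(at_boundary$covered, 36L)

  one_out <- obs
  one_out[36] <- one_out[36] + 3 * se[36]
  cv <- moe_coverage(ps(one_out, obs, se))
  expect_identical(cv$covered, 35L)
  expect_identical(cv$total, 36L)

  jittered <- ps(obs + rnorm(36, 0, 15), obs, se)
  zs <- c(0.5, 1, 1.96, 3)
  counts <- vapply(zs, function(z) moe_coverage(jittered, z)$covered, integer(1))
  expect_true(all(diff(counts) >= 0))

  expect_error(moe_coverage(ps(obs, obs)), "standard error")
})

test_that("compare_models ranks models and runs the restricted head-to-head", {
  # observations generated under the orthogonal rule plus small noise
  shape_D <- c(house = 95.2, square = 44.9, triangle = 46.8)
  texture_D <- c(solid = 43.9, tilted_pound = 111.9, dots = 69.5)
  pairs <- expand.grid(
    shape = names(shape_D), texture = names(texture_D),
    ss = c(2L, 5L, 10L, 20L), stringsAsFactors = FALSE
  )
  rt0 <- 560
  truth <- rt0 + combine_orthogonal(shape_D[pairs$shape], texture_D[pairs$texture]) * log(pairs$ss)
  set.seed(123)
  obs <- truth + rnorm(nrow(pairs), 0, 4)
  cond <- paste(pairs$shape, pairs$texture, sep = "_")

  mk <- function(model, f) {
    prediction_set(
      model, cond, pairs$ss,
      rt0 + f(shape_D[pairs$shape], texture_D[pairs$texture]) * log(pairs$ss),
      obs, se_observed = rep(4, nrow(pairs)), n_free_params = 0L
    )
  }
  preds <- list(
    best_feature = mk("best_feature", combine_best),
    orthogonal = mk("orthogonal", combine_orthogonal),
    collinear = mk("collinear", combine_collinear)
  )
  rep_full <- compare_models(preds)
  expect_identical(rep_full$winner, "orthogonal")
  expect_equal(rep_full$models$rel_likelihood[1], 1)
  expect_true(all(rep_full$models$rel_likelihood <= 1))
  expect_identical(nrow(rep_full$pairwise), 2L)
  expect_true(all(rep_full$pairwise$df == 35L))
  # equal free parameters: R^2 and AIC must rank the models identically
  expect_identical(order(rep_full$models$aic), order(-rep_full$models$r2))

  # restricted model at set size 20 only
  at20 <- pairs$ss == 20L
  recip <- prediction_set(
    "reciprocal", cond[at20], 20L,
    obs[at20] + rnorm(sum(at20), 0, 3), obs[at20],
    se_observed = rep(4, sum(at20)), n_free_params = 3L
  )
  rep_r <- compare_models(c(preds, list(reciprocal = recip)))
  expect_identical(rep_r$winner, "orthogonal")
  expect_named(rep_r$restricted, "reciprocal")
  expect_identical(rep_r$restricted$reciprocal$points, 9L)
  expect_setequal(rep_r$restricted$reciprocal$models$model, c("orthogonal", "reciprocal"))

  single <- compare_models(list(orthogonal = preds$orthogonal))
  expect_identical(single$winner, "orthogonal")
  expect_equal(single$models$rel_likelihood, 1)

  misaligned <- preds
  misaligned$collinear <- ps(obs[1:10], obs[1:10] + 1, model = "collinear", ss = rep(2L, 10))
  expect_error(compare_models(misaligned, restricted = character(0)), "misaligned")
})

test_that("the reference efficiency tables rank the orthogonal rule first", {
  d <- demo_fixture_comparison()
  expect_identical(d$winner, "orthogonal")
  expect_equal(unname(d$mad["orthogonal"]), 5.339, tolerance = 1e-3)
  expect_equal(unname(d$mad["collinear"]), 8.145, tolerance = 1e-3)
  expect_equal(unname(d$mad["best_feature"]), 14.233, tolerance = 1e-3)
  expect_identical(nrow(d$table), 27L) # 9 pairings x 3 models
})
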