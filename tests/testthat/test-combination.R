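test_that("contrast is the reciprocal slope and rejects non-positive slopes", {
  expect_equal(contrast_from_slope(1), 1)
  expect_equal(contrast_from_slope(95.2), 1 / 95.2)
  expect_equal(contrast_from_slope(50, alpha = 2), 0.04)
  expect_error(contrast_from_slope(0), "positive")
  expect_error(contrast_from_slope(-10), "positive")
})

test_that("the three combination rules give their closed-form values", {
  # reference single-feature slopes: house 95.2, tilted-pound texture 111.9
  expect_equal(combine_best(95.2, 111.9), 95.2)
  expect_equal(combine_best(46.8, 43.9), 43.9)
  expect_equal(combine_orthogonal(95.2, 111.9), 72.50944, tolerance = 1e-6)
  expect_equal(combine_collinear(95.2, 111.9), 51.43834, tolerance = 1e-6)
  expect_equal(combine_collinear(44.9, 69.5), 27.27753, tolerance = 1e-6)

  # equal inputs collapse to the documented constants
  d <- 61.3
  expect_equal(combine_best(d, d), d)
  expect_equal(combine_orthogonal(d, d), d / sqrt(2))
  expect_equal(combine_collinear(d, d), d / 2)

  for (f in list(combine_best, combine_orthogonal, combine_collinear)) {
    expect_error(f(0, 50), "positive")
    expect_error(f(50, -1), "positive")
  }
})

test_that("combination rules are symmetric, homogeneous, ordered, and have the right limit", {
  set.seed(99)
  ds <- runif(200, 1, 300)
  dt <- runif(200, 1, 300)
  best <- combine_best(ds, dt)
  orth <- combine_orthogonal(ds, dt)
  coll <- combine_collinear(ds, dt)

  expect_identical(best, combine_best(dt, ds))
  expect_identical(orth, combine_orthogonal(dt, ds))
  expect_identical(coll, combine_collinear(dt, ds))

  # collinear <= orthogonal <= best, strictly for finite distinct inputs
  expect_true(all(coll < orth))
  expect_true(all(orth < best))

  for (f in list(combine_best, combine_orthogonal, combine_collinear)) {
    expect_equal(f(2.5 * ds, 2.5 * dt), 2.5 * f(ds, dt), tolerance = 1e-12)
    # as one slope grows unboundedly its contrast vanishes and the other wins
    expect_equal(f(ds, 1e9 * ds), ds, tolerance = 1e-6)
  }
})

test_that("RT prediction follows the logarithmic law", {
  expect_equal(predict_rt(600, 50, 1), 600)
  expect_equal(predict_rt(600, 50, 10), 600 + 50 * log(10)) # ~715.13
  expect_equal(predict_rt(640, 0, c(1, 5, 20)), rep(640, 3))
  expect_error(predict_rt(600, 50, 0), ">= 1")
})

test_that("combine_efficiencies maps pairings through named slope vectors", {
  pairs <- tibble::tibble(
    distractor_shape = c("house", "square"),
    distractor_texture = c("tilted_pound", "dots")
  )
  out <- combine_efficiencies(
    pairs,
    shape_D = c(house = 95.2, square = 44.9),
    texture_D = c(tilted_pound = 111.9, dots = 69.5)
  )
  expect_identical(nrow(out), 6L) # 2 pairings x 3 models
  orth <- out[out$model == "orthogonal", ]
  expect_equal(orth$D_overall, combine_orthogonal(c(95.2, 44.9), c(111.9, 69.5)))
  expect_error(
    combine_efficiencies(pairs, shape_D = c(house = 95.2), texture_D = c(dots = 1)),
    "square"
  )
})

test_that("the reciprocal-of-RT fit recovers an exact linear system", {
  set.seed(5)
  rt_shape <- seq(650, 850, length.out = 9)
  rt_texture <- sample(seq(690, 910, length.out = 9))
  recip_both <- 0.5 / rt_shape + 0.3 / rt_texture + 1e-4
  rt_both <- 1 / recip_both

  fit <- fit_reciprocal(rt_shape, rt_texture, rt_both)
  expect_equal(fit$a, 0.5, tolerance = 1e-8)
  expect_equal(fit$b, 0.3, tolerance = 1e-8)
  expect_equal(fit$c, 1e-4, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  expect_identical(fit$fixed_set_size, 20L)
  expect_equal(predict_reciprocal(fit, rt_shape, rt_texture), rt_both, tolerance = 1e-8)
})

test_that("degenerate reciprocal fits are refused", {
  expect_error(
    fit_reciprocal(rep(700, 9), seq(690, 910, length.out = 9), seq(600, 760, length.out = 9)),
    "collinear"
  )
  expect_error(fit_reciprocal(1:3 * 100, 1:3 * 110, 1:3 * 120), "at least 4")
})

test_that("reciprocal predictions handle weight edge cases", {
  unit_fit <- structure(
    list(a = 1, b = 0, c = 0, rss = 0, fixed_set_size = 20L, n = 9L),
    class = "reciprocal_fit"
  )
  expect_equal(predict_reciprocal(unit_fit, c(650, 700), c(800, 820)), c(650, 700))

  const_fit <- structure(
    list(a = 0, b = 0, c = 1 / 700, rss = 0, fixed_set_size = 20L, n = 9L),
    class = "reciprocal_fit"
  )
  expect_equal(predict_reciprocal(const_fit, c(650, 900), c(800, 600)), c(700, 700))

  neg_fit <- structure(
    list(a = 0, b = 0, c = -1, rss = 0, fixed_set_size = 20L, n = 9L),
    class = "reciprocal_fit"
  )
  expect_error(predict_reciprocal(neg_fit, 650, 800), "non-positive")
})
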