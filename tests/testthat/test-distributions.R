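test_that("point specs are degenerate and truncation bounds are honoured", {
  expect_equal(sample_dist(dist_spec("point", value = 5), 100), rep(5, 100))
  set.seed(11)
  x <- sample_dist(dist_spec("normal", mean = 0.015, sd = 0.003, lower = 0), 1e4)
  expect_true(all(x >= 0))
  set.seed(12)
  y <- sample_dist(dist_spec("truncated_normal", mean = 0, sd = 1,
                             lower = -0.5, upper = 0.25), 1e4)
  expect_true(all(y >= -0.5 & y <= 0.25))
})

test_that("empirical means of 1e5 draws match analytic means for every family", {
  specs <- list(
    dist_spec("point", value = 3.7),
    dist_spec("uniform", min = 2, max = 8),
    dist_spec("normal", mean = 10, sd = 2),
    dist_spec("normal", mean = 0.01, sd = 0.02, lower = 0, upper = 1),
    dist_spec("truncated_normal", mean = 5, sd = 4, lower = 0),
    dist_spec("triangular", min = 1, mode = 3, max = 9),
    dist_spec("pert", min = 1, mode = 3, max = 9),
    dist_spec("lognormal", meanlog = 1, sdlog = 0.5),
    dist_spec("lognormal", meanlog = 0, sdlog = 1, upper = 2),
    dist_spec("empirical", values = c(1, 2, 2, 7), lower = 1.5)
  )
  set.seed(99)
  for (spec in specs) {
    x <- sample_dist(spec, 1e5)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - dist_mean(spec)), max(4 * se, 1e-12),
              label = paste("family", spec$family))
  }
  # the CLT bound of the plain-normal case specifically
  set.seed(100)
  x <- sample_dist(dist_spec("normal", mean = 10, sd = 2), 1e5)
  expect_lt(abs(mean(x) - 10), 3 * 2 / sqrt(1e5))
})

test_that("sampling is reproducible under a fixed seed", {
  spec <- dist_spec("pert", min = 0, mode = 2, max = 10)
  set.seed(42)
  a <- sample_dist(spec, 1000)
  set.seed(42)
  b <- sample_dist(spec, 1000)
  expect_identical(a, b)
})

test_that("invalid specifications are rejected with informative errors", {
  expect_error(dist_spec("normal", mean = 1, sd = 0),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("normal", mean = 1, sd = 1, lower = 2, upper = 1),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("triangular", min = 3, mode = 2, max = 5),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("point", value = 1, extra = 2),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("uniform", min = 0, max = 1, lower = 0.2),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("empirical", values = numeric(0)),
               class = "aquaburden_invalid_parameter")
  expect_error(dist_spec("gamma", shape = 1),
               class = "aquaburden_invalid_parameter")
})

test_that("spec_from_c90 inverts the mean-plus-C90 reporting convention", {
  spec <- spec_from_c90(9.50, 8.62, 10.34)
  expect_equal(spec$family, "normal")
  expect_equal(spec$params$mean, 9.50)
  expect_equal(spec$params$sd, 0.5229, tolerance = 1e-3)
  # analytic quantiles of the constructed normal reproduce the interval
  q <- qnorm(c(0.05, 0.95), spec$params$mean, spec$params$sd)
  expect_lt(abs(q[1] - 8.62), 0.05)
  expect_lt(abs(q[2] - 10.34), 0.05)

  expect_equal(spec_from_c90(5, 5, 5),
               dist_spec("point", value = 5))
  expect_error(spec_from_c90(10, 12, 8), class = "aquaburden_invalid_c90")
})
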