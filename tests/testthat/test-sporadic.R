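test_that("attributable risk is the exposed-minus-unexposed difference", {
  expect_equal(attributable_risk(0.040, 0.025), 0.015) # swimming AGI
  expect_equal(attributable_risk(0.053, 0.038), 0.015) # fishing AGI
  expect_equal(attributable_risk(0.3, 0.3), 0)
  expect_equal(attributable_risk(0.02, 0.05), -0.03)
  expect_equal(attributable_risk(0.02, 0.05, truncate_at_zero = TRUE), 0)
  expect_error(attributable_risk(1.2, 0.5))
})

test_that("expected cases are events times attributable risk, sign included", {
  expect_equal(expected_cases(1928.9e6, 0.015), 28.9335e6)
  expect_equal(expected_cases(1105.1e6, 0.015), 16.5765e6)
  expect_equal(expected_cases(0, 0.5), 0)
  expect_equal(expected_cases(1e6, -0.002), -2000) # negative draws propagate
  # monotone in both arguments
  expect_gte(expected_cases(2e6, 0.01), expected_cases(1e6, 0.01))
  expect_gte(expected_cases(1e6, 0.02), expected_cases(1e6, 0.01))
})

test_that("severity split conserves cases", {
  s <- split_severity(50.95e6, 0.072)
  expect_equal(s$moderate_cases, 3.6684e6)
  expect_equal(s$mild_cases, 47.2816e6)
  expect_equal(s$mild_cases + s$moderate_cases, 50.95e6)
  expect_equal(split_severity(10, 0), tibble::tibble(mild_cases = 10,
                                                     moderate_cases = 0))
  expect_equal(split_severity(10, 1), tibble::tibble(mild_cases = 0,
                                                     moderate_cases = 10))
})

test_that("overall moderate share is the case-weighted mean of the fractions", {
  # published per-illness annual case means and moderate fractions
  tbl <- tibble::tibble(
    illness = c("agi", "respiratory", "eye", "ear", "skin"),
    total_cases = c(50.95, 9.22, 7.55, 6.87, 12.06) * 1e6,
    moderate_frac = c(0.072, 0.137, 0.104, 0.243, 0.054)
  )
  tbl$moderate_cases <- tbl$total_cases * tbl$moderate_frac
  expect_equal(moderate_share_overall(tbl), 0.0927, tolerance = 5e-3)
  expect_equal(moderate_share_overall(tbl[1, ]), 0.072)
  zero <- tbl
  zero$moderate_cases <- 0
  expect_equal(moderate_share_overall(zero), 0)
  expect_error(moderate_share_overall(tibble::tibble(total_cases = 0,
                                                     moderate_cases = 0)),
               class = "aquaburden_no_cases")
})

test_that("absent activity-illness pairs contribute no cases and no variance", {
  sim <- run_simulation(tiny_scenario(), n_iterations = 50, seed = 3)
  # tiny scenario declares only swimming AGI
  cl <- sim$draws$cases_by_illness
  expect_setequal(unique(cl$illness), "agi")
  expect_equal(nrow(sim$tables$cases), 2) # swimming + total
})

test_that("turning on AR truncation never decreases mean cases and barely moves us2007 costs", {
  sc <- us2007_scenario()
  n <- 20000
  off <- run_simulation(sc, n_iterations = n, seed = 5,
                        truncate_negative_ar = FALSE)
  on <- run_simulation(sc, n_iterations = n, seed = 5,
                       truncate_negative_ar = TRUE)
  cases_off <- dplyr::summarise(
    dplyr::group_by(off$draws$cases_by_illness, draw),
    total = sum(total_cases))$total
  cases_on <- dplyr::summarise(
    dplyr::group_by(on$draws$cases_by_illness, draw),
    total = sum(total_cases))$total
  # same seed, same parameter draws: truncation acts draw-by-draw
  expect_true(all(cases_on >= cases_off - 1e-9))
  expect_gte(mean(cases_on), mean(cases_off))
  rel_change <- abs(mean(on$draws$grand_total) / mean(off$draws$grand_total) - 1)
  expect_lt(rel_change, 0.05)
})
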