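test_that("underreporting multipliers scale observed counts linearly", {
  expect_equal(adjust_for_underreporting(100, 25.5), 2550)
  expect_equal(adjust_for_underreporting(40, 1.1), 44)   # vibriosis
  expect_equal(adjust_for_underreporting(7, 1.0), 7)     # Naegleria fowleri
  expect_error(adjust_for_underreporting(10, 0.9),
               class = "aquaburden_invalid_multiplier")
  # linearity and ordering
  expect_equal(adjust_for_underreporting(200, 25.5),
               2 * adjust_for_underreporting(100, 25.5))
  expect_gt(adjust_for_underreporting(50, 25.5),
            adjust_for_underreporting(50, 1.1))
})

test_that("severe outcomes apply fractions and the doubling correction", {
  out <- severe_outcomes(1000, 0.05, 0.001, 2.0)
  expect_equal(out$hospitalizations, 100)
  expect_equal(out$deaths, 2)
  expect_equal(severe_outcomes(500, 0, 0, 2),
               tibble::tibble(community_cases = 500, hospitalizations = 0,
                              deaths = 0))
  # doubling observed cases doubles both outcomes
  a <- severe_outcomes(300, 0.1, 0.01)
  b <- severe_outcomes(600, 0.1, 0.01)
  expect_equal(b$hospitalizations, 2 * a$hospitalizations)
  expect_equal(b$deaths, 2 * a$deaths)
  expect_error(severe_outcomes(10, 1.5, 0))
})

test_that("aggregation sums component-wise", {
  df <- tibble::tibble(hospitalizations = c(10, 5), deaths = c(1, 0))
  expect_equal(aggregate_severe(df),
               tibble::tibble(hospitalizations = 15, deaths = 1))
  expect_equal(aggregate_severe(df[2, ]),
               tibble::tibble(hospitalizations = 5, deaths = 0))
  expect_equal(aggregate_severe(df[0, ]),
               tibble::tibble(hospitalizations = 0, deaths = 0))
})

test_that("per-pathogen pipeline stage reproduces the hand computation", {
  sim <- point_estimate(tiny_scenario())
  sev <- sim$draws$severe_totals
  expect_equal(sev$hospitalizations, 51)   # 10 * 25.5 * 0.1 * 2
  expect_equal(sev$deaths, 5.1)            # 10 * 25.5 * 0.01 * 2
  expect_true(all(sim$full_draws$severe$hospitalizations >= 0))
})

test_that("pathogen CSV tables load and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pathogen,observed_cases,community_multiplier,hosp_fraction,death_fraction,severe_correction",
               "cryptosporidium,32,25.5,0.13,0.004,2",
               "vibrio,40,1.1,0.30,0.05,2"), f)
  tbl <- read_pathogen_table(f)
  expect_equal(nrow(tbl), 2)
  writeLines(c("pathogen,observed_cases,community_multiplier,hosp_fraction,death_fraction,severe_correction",
               "x,10,0.5,0.1,0.01,2"), f)
  expect_error(read_pathogen_table(f), class = "aquaburden_invalid_multiplier")
})
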