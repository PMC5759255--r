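test_that("generated scenarios validate, round-trip, and are deterministic in the seed", {
  for (seed in 1:4) {
    synth <- generate_scenario(seed, n_activities = 2, n_illnesses = 2,
                               n_pathogens = 1)
    expect_s3_class(synth$scenario, "scenario_config")
    f <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(synth$scenario, f)
    expect_equal(read_scenario(f), synth$scenario)
  }
  a <- generate_scenario(11, 3, 2, 2)
  b <- generate_scenario(11, 3, 2, 2)
  expect_equal(a$scenario, b$scenario)
  expect_equal(a$truth, b$truth)
})

test_that("the generator can emulate the packaged scenario's shape", {
  synth <- generate_scenario(5, n_activities = 6, n_illnesses = 5,
                             n_pathogens = 8)
  expect_length(synth$scenario$activities, 6)
  expect_length(synth$scenario$pathogens, 8)
  expect_setequal(unique(vapply(synth$scenario$severity, `[[`, "", "illness")),
                  c("agi", "respiratory", "eye", "ear", "skin"))
  mult <- vapply(synth$scenario$pathogens, `[[`, 0, "community_multiplier")
  expect_true(all(mult %in% c(1, 1.1, 25.5)))
})

test_that("closed-form expectations factorize products of independent means", {
  # one activity, one illness, point person-days D and AR a: cases = D * a
  sc <- tiny_scenario()
  truth <- analytic_expectation(sc)
  v <- setNames(truth$value, truth$cell)
  expect_equal(v[["person_days.swimming"]], 3e6)
  expect_equal(v[["cases.swimming.agi"]], 3e6 * 0.03)
  expect_equal(v[["moderate_cases_total"]], 9e3)
  expect_equal(v[["hospitalizations"]], 51)
  expect_equal(v[["cost.severe.death_vsl"]], 5.1 * 7e6)
  expect_equal(v[["grand_total"]],
               v[["cost.mild.total"]] + v[["cost.moderate.total"]] +
                 v[["cost.severe.total"]])
  # no closed form under AR truncation
  sc$options$truncate_negative_ar <- TRUE
  expect_error(analytic_expectation(sc), class = "aquaburden_no_closed_form")
})

test_that("Monte Carlo means recover the analytic truth within 4 standard errors", {
  synth <- generate_scenario(7, n_activities = 3, n_illnesses = 3,
                             n_pathogens = 4)
  sim <- run_simulation(synth$scenario, n_iterations = 1e5, seed = 70,
                        keep_draws = TRUE)
  mc <- mc_expectation_cells(sim)
  j <- dplyr::inner_join(synth$truth, mc, by = "cell")
  expect_equal(nrow(j), nrow(synth$truth))
  dev <- abs(j$mc_mean - j$value) / pmax(j$mc_se, 1e-12)
  expect_lt(max(dev[j$mc_se > 0]), 4)
  # cells with zero Monte Carlo variance must match exactly
  exact <- j$mc_se == 0
  if (any(exact)) expect_equal(j$mc_mean[exact], j$value[exact])
})
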