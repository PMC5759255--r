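test_that("CPI adjustment multiplies by the keyed factor", {
  cpi <- us2007_scenario()$costs$cpi_factors
  expect_equal(inflation_adjust(100, 2007, "medical_services", cpi), 100)
  expect_equal(inflation_adjust(0, 2007, "wages", cpi), 0)
  # a 2001 medical-services amount restated in 2007 dollars
  expect_equal(inflation_adjust(3.3e6, 2001, "medical_services", cpi), 3.894e6)
  expect_error(inflation_adjust(1, 1999, "medical_services", cpi),
               class = "aquaburden_unknown_cpi_key")
})

test_that("component, productivity, mortality and sequelae terms multiply out", {
  expect_equal(component_cost(1e6, 0.5, 10), 5e6)
  expect_equal(component_cost(1e6, 0, 100), 0)
  expect_error(component_cost(1, 1.5, 1))
  expect_equal(productivity_cost(1e6, 0.4, 8, 20), 64e6)
  expect_equal(productivity_cost(1e6, 0.4, 0, 20), 0)
  expect_equal(mortality_cost(0, 7e6), 0)
  expect_equal(mortality_cost(1, 7.4e6), 7.4e6)

  hosp <- tibble::tibble(pathogen = "campylobacter", hospitalizations = 10)
  sq <- tibble::tibble(pathogen = "campylobacter", probability = 0.01,
                       excess_cost = 1e5)
  expect_equal(sequelae_cost(hosp, sq), 1e4)
  expect_equal(sequelae_cost(hosp, sq[0, ]), 0)
  expect_error(sequelae_cost(hosp, dplyr::mutate(sq, pathogen = "unknown")),
               class = "aquaburden_invalid_parameter")
})

test_that("tier totals equal their component sums (published component values)", {
  mod <- cost_breakdown("moderate", otc = 33.5e6, rx = 126.0e6, hcp = 615.0e6,
                        ed = 924.9e6, productivity = 201.1e6)
  expect_equal(mod$total, 1900.5e6)
  expect_equal((mod$hcp + mod$ed) / mod$total, 0.81, tolerance = 5e-3)

  sev <- cost_breakdown("severe", otc = 0.004e6, rx = 0.03e6, hcp = 0.16e6,
                        ed = 0.22e6, hospital = 6.79e6, sequelae = 0.38e6,
                        productivity = 0.31e6, death_vsl = 225.79e6)
  expect_equal(sev$total, 233.684e6)
  expect_equal(round(sev$total / 1e4) / 100, 233.68)
  expect_equal(round(100 * sev$death_vsl / sev$total), 97)

  zero <- cost_breakdown("mild")
  expect_equal(zero$total, 0)
})

test_that("the tier composition rule is enforced", {
  expect_error(cost_breakdown("mild", hcp = 1),
               class = "aquaburden_invalid_parameter")
  expect_error(cost_breakdown("mild", death_vsl = 1),
               class = "aquaburden_invalid_parameter")
  expect_error(cost_breakdown("moderate", hospital = 1),
               class = "aquaburden_invalid_parameter")
  expect_no_error(cost_breakdown("moderate", hcp = 1, ed = 1))
  expect_no_error(cost_breakdown("severe", hospital = 1, death_vsl = 1,
                                 sequelae = 1))
})

test_that("severity_cost composes tiers and is homogeneous in unit costs", {
  util <- list(p_otc = 0.5, p_rx = 0.1, p_hcp = 0.8, p_ed = 0.2,
               p_work_loss = 0.4, lost_hours = 2)
  uc <- list(otc = 6, rx = 30, hcp = 90, ed = 700, wage = 20, vsl = 7e6)
  mild <- severity_cost("mild", 1000, util, uc)
  expect_equal(mild$otc, 1000 * 0.5 * 6)
  expect_equal(mild$hcp, 0)
  expect_equal(mild$total, mild$otc + mild$rx + mild$productivity)

  mod <- severity_cost("moderate", 1000, util, uc)
  expect_equal(mod$ed, 1000 * 0.2 * 700)

  sev <- severity_cost("severe", 100, util, uc, hospital = 8e5,
                       sequelae = 1e4, deaths = 2)
  expect_equal(sev$death_vsl, 1.4e7)
  expect_equal(sev$total, sev$otc + sev$rx + sev$hcp + sev$ed + sev$hospital +
                 sev$sequelae + sev$productivity + sev$death_vsl)

  k <- 3
  uck <- lapply(uc, `*`, k)
  expect_equal(severity_cost("moderate", 1000, util, uck)$total,
               k * mod$total)
})

test_that("per-case cost divides and guards against zero cases", {
  expect_equal(per_case_cost(756.7e6, 80.1e6), 9.447, tolerance = 1e-3)
  expect_equal(per_case_cost(0, 10), 0)
  expect_equal(per_case_cost(5, 1), 5)
  expect_error(per_case_cost(1, 0), class = "aquaburden_no_cases")
})
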