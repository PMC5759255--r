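test_that("recreator counts scale participation by the census bases", {
  # 2007 US bases: 233.5M adults, 63.3M children
  expect_equal(recreators_over16(0.237, 233.5e6), 55.3395e6) # fishing
  expect_equal(recreators_over16(0.415, 233.5e6), 96.9025e6) # swimming
  expect_equal(recreators_over16(0, 5e8), 0)
  expect_equal(recreators_under16(0.888, 63.3e6), 56.2104e6) # swimming
  expect_equal(recreators_under16(0.049, 63.3e6), 3.1017e6)  # canoeing
  expect_equal(recreators_under16(1, 63.3e6), 63.3e6)
  expect_error(recreators_over16(-0.1, 1e6),
               class = "aquaburden_invalid_parameter")
  expect_equal(recreators_under16_from_ratio(50e6, 0.4), 20e6)
})

test_that("person-days are recreators times days per recreator", {
  expect_equal(person_days((96.9 + 56.3) * 1e6, 12.6), 1930.32e6)
  expect_equal(person_days((55.3 + 20.4) * 1e6, 14.6), 1105.22e6)
  expect_equal(person_days(1e9, 0), 0)
})

test_that("total events sum over activities, invariant to order and partition", {
  df <- tibble::tibble(activity = c("a", "b", "c"),
                       person_days = c(1.5e9, 2.2e8, 3e7))
  expect_equal(total_events(df), 1.75e9)
  expect_equal(total_events(df[c(3, 1, 2), ]), total_events(df))
  expect_equal(total_events(df[1, ]) + total_events(df[2:3, ]),
               total_events(df))
  expect_equal(total_events(df[0, ]), 0)
})

test_that("exposure is homogeneous of degree one in each population base", {
  params <- tibble::tibble(activity = c("swim", "fish"),
                           participation = c(0.4, 0.2),
                           under16_share = c(0.8, 0.3),
                           mean_days = c(12, 15))
  pop <- list(adult_population = 2e8, child_population = 6e7)
  base <- compute_exposure(params, pop)
  k <- 2.5
  scaled <- compute_exposure(params, lapply(pop, `*`, k))
  expect_equal(scaled$person_days, k * base$person_days)
  expect_equal(base$person_days,
               (base$recreators_over16 + base$recreators_under16) *
                 params$mean_days)
})

test_that("point-mass evaluation of us2007 reproduces the published exposure table", {
  pt <- point_estimate(us2007_scenario())
  pd <- pt$tables$exposure[pt$tables$exposure$quantity == "person_days", ]
  printed <- c(swimming = 1928.9e6, kayaking = 84.4e6, rowing = 55.8e6,
               canoeing = 121.1e6, motor_boating = 745.8e6,
               fishing = 1105.1e6, total = 4041e6)
  for (act in names(printed)) {
    got <- pd$mean[pd$activity == act]
    expect_lt(abs(got / printed[[act]] - 1), 0.002,
              label = paste("person-days for", act))
  }
})
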