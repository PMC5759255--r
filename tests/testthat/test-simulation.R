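test_that("C90 summaries use linear interpolation between order statistics", {
  s <- summarize_c90(1:100)
  expect_equal(s$mean, 50.5)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  expect_equal(summarize_c90(rep(3.2, 10)),
               tibble::tibble(mean = 3.2, p5 = 3.2, p95 = 3.2, n_draws = 10L))
  expect_error(summarize_c90(numeric(0)), class = "aquaburden_no_draws")
  set.seed(8)
  z <- summarize_c90(rnorm(1e5))
  expect_lt(abs(z$p5 - qnorm(0.05)), 0.03)
  expect_lt(abs(z$p95 - qnorm(0.95)), 0.03)
})

test_that("identical scenario, iterations and seed give bit-identical output", {
  sc <- tiny_scenario()
  sc$activities[[1]]$participation_over16 <-
    dist_spec("normal", mean = 0.2, sd = 0.02, lower = 0, upper = 1)
  a <- run_simulation(sc, n_iterations = 500, seed = 123)
  b <- run_simulation(sc, n_iterations = 500, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$tables, b$tables)
  c <- run_simulation(sc, n_iterations = 500, seed = 124)
  expect_false(identical(a$draws$grand_total, c$draws$grand_total))
})

test_that("a point-mass scenario collapses the Monte Carlo to its oracle", {
  sc <- as_point_scenario(generate_scenario(3, 2, 2, 2)$scenario)
  sim <- run_simulation(sc, n_iterations = 10, seed = 99, keep_draws = TRUE)
  # every draw identical
  expect_length(unique(sim$draws$grand_total), 1)
  expect_equal(sim$tables$grand_total$p5, sim$tables$grand_total$mean)
  expect_equal(sim$tables$grand_total$p95, sim$tables$grand_total$mean)
  # and equal to the closed-form expectation, cell by cell
  truth <- analytic_expectation(sc)
  mc <- mc_expectation_cells(sim)
  j <- dplyr::inner_join(truth, mc, by = "cell")
  expect_equal(nrow(j), nrow(truth))
  expect_equal(j$mc_mean, j$value, tolerance = 1e-9)
  expect_true(all(j$mc_se < 1e-6 * (abs(j$value) + 1)))
})

test_that("single-iteration runs work and per-draw conservation holds", {
  one <- run_simulation(tiny_scenario(), n_iterations = 1, seed = 4)
  expect_equal(one$tables$grand_total$n_draws, 1L)

  sim <- run_simulation(us2007_scenario(), n_iterations = 300, seed = 17)
  tc <- sim$draws$tier_costs
  comp_sum <- tc$otc + tc$rx + tc$hcp + tc$ed + tc$hospital + tc$sequelae +
    tc$productivity + tc$death_vsl
  expect_equal(tc$total, comp_sum)
  # mild/moderate zero-composition cells
  expect_true(all(tc$hcp[tc$tier == "mild"] == 0))
  expect_true(all(tc$death_vsl[tc$tier != "severe"] == 0))
  expect_true(all(tc$hospital[tc$tier == "moderate"] == 0))
  # tier totals sum to the grand total draw by draw
  by_draw <- dplyr::summarise(dplyr::group_by(tc, draw), s = sum(total))
  expect_equal(by_draw$s, sim$draws$grand_total)
})

test_that("the grand-total mean converges with iteration count", {
  sc <- us2007_scenario()
  small <- run_simulation(sc, n_iterations = 1e4, seed = 31)
  big <- run_simulation(sc, n_iterations = 1e5, seed = 32)
  se_small <- stats::sd(small$draws$grand_total) / sqrt(1e4)
  expect_lt(abs(mean(small$draws$grand_total) - mean(big$draws$grand_total)),
            4 * se_small)
})

test_that("render_tables writes the report files and JSON round-trips", {
  sim <- run_simulation(tiny_scenario(), n_iterations = 100, seed = 6)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report")
  paths <- render_tables(sim, out)
  expect_true(all(file.exists(paths)))
  expect_length(list.files(out, pattern = "\\.csv$"), 3)
  back <- jsonlite::fromJSON(paths[["summary"]])
  expect_equal(back$costs$mean, sim$tables$costs$mean)
  expect_equal(back$grand_total$mean, sim$tables$grand_total$mean)
  manifest <- readLines(paths[["manifest"]])
  expect_true(any(grepl("seed: 6", manifest)))
})

test_that("tidy, glance and autoplot expose the summaries", {
  sim <- run_simulation(tiny_scenario(), n_iterations = 50, seed = 2)
  td <- tidy(sim)
  expect_true(all(c("table", "term", "mean", "p5", "p95") %in% names(td)))
  expect_true("grand_total" %in% td$term)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_iterations, 50)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(sim, table = "cases"), "ggplot")
})
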