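# Synthetic scenarios with known ground truth. Because every output cell of
# the pipeline is a sum of products of independently sampled factors, its
# expectation is the same sum of products of the factor means; the generator
# therefore carries an analytic truth table against which the Monte Carlo
# engine can be verified on any randomly generated parameter book.

cost_mean <- function(spec, cpi) {
  m <- dist_mean(spec)
  if (!is.null(spec$source_year)) {
    m <- inflation_adjust(m, spec$source_year, spec$series, cpi)
  }
  m
}

#' Closed-form expected outputs of a scenario
#'
#' Computes the exact expectation of every product-chain output cell --
#' person-days, case counts, severe outcomes, tier cost components, grand
#' total -- as products and sums of the component distribution means
#' (parameters are sampled independently). Ratio-type outputs (per-case
#' costs, moderate share) are intentionally not tabulated: the expectation
#' of a ratio is not the ratio of expectations.
#'
#' Expectations assume the untruncated attributable-risk analysis; there is
#' no closed form under truncation (the expectation of a clamped difference
#' of two clamped draws), so `truncate_negative_ar = TRUE` scenarios are
#' rejected.
#'
#' @param scenario A `scenario_config` or `synthetic_scenario`.
#' @return A tibble with columns `cell` and `value`.
#' @export
analytic_expectation <- function(scenario) {
  if (inherits(scenario, "synthetic_scenario")) scenario <- scenario$scenario
  scenario <- as_scenario_config(scenario)
  if (isTRUE(scenario$options$truncate_negative_ar)) {
    abort("no closed form: analytic expectations require truncate_negative_ar = false",
          class = "aquaburden_no_closed_form")
  }
  cpi <- scenario$costs$cpi_factors
  pop <- scenario$population
  cells <- list()
  add <- function(cell, value) cells[[length(cells) + 1]] <<- tibble(cell = cell,
                                                                     value = value)

  pd <- numeric(0)
  for (a in scenario$activities) {
    rec <- dist_mean(a$participation_over16) * pop$adult_population +
      dist_mean(a$under16_share) * pop$child_population
    pd[[a$name]] <- rec * dist_mean(a$mean_days_per_year)
    add(paste0("person_days.", a$name), pd[[a$name]])
  }
  add("total_events", sum(pd))

  sev_profile <- setNames(scenario$severity, map_chr(scenario$severity, "illness"))
  ill_present <- unique(map_chr(scenario$risks, "illness"))
  cases_ill <- setNames(numeric(length(ill_present)), ill_present)
  mild_ill <- cases_ill
  mod_ill <- cases_ill
  for (r in scenario$risks) {
    ar <- dist_mean(r$p_exposed) - dist_mean(r$p_unexposed)
    cs <- pd[[r$activity]] * ar
    add(paste0("cases.", r$activity, ".", r$illness), cs)
    mf <- dist_mean(sev_profile[[r$illness]]$moderate_fraction)
    cases_ill[[r$illness]] <- cases_ill[[r$illness]] + cs
    mod_ill[[r$illness]] <- mod_ill[[r$illness]] + cs * mf
    mild_ill[[r$illness]] <- mild_ill[[r$illness]] + cs * (1 - mf)
  }
  for (ill in ill_present) add(paste0("cases_total.", ill), cases_ill[[ill]])
  add("cases_total", sum(cases_ill))
  add("mild_cases_total", sum(mild_ill))
  add("moderate_cases_total", sum(mod_ill))

  hosp <- numeric(0)
  deaths <- numeric(0)
  hospital_cost <- 0
  seq_cost <- 0
  for (p in scenario$pathogens) {
    community <- p$observed_cases * p$community_multiplier
    hosp[[p$name]] <- community * dist_mean(p$hosp_fraction) * p$severe_correction
    deaths[[p$name]] <- community * dist_mean(p$death_fraction) * p$severe_correction
    add(paste0("hospitalizations.", p$name), hosp[[p$name]])
    add(paste0("deaths.", p$name), deaths[[p$name]])
    hospital_cost <- hospital_cost + hosp[[p$name]] * cost_mean(p$hosp_cost, cpi)
    for (sq in p$sequelae) {
      seq_cost <- seq_cost + hosp[[p$name]] * dist_mean(sq$probability) *
        cost_mean(sq$excess_cost, cpi)
    }
  }
  add("hospitalizations", sum(hosp))
  add("deaths", sum(deaths))

  co <- scenario$costs
  u_otc <- cost_mean(co$otc_per_user, cpi)
  u_rx <- cost_mean(co$rx_per_user, cpi)
  u_hcp <- cost_mean(co$hcp_visit, cpi)
  u_ed <- cost_mean(co$ed_visit, cpi)
  u_wage <- cost_mean(co$wage_per_hour, cpi)
  u_vsl <- cost_mean(co$vsl, cpi)
  sv <- co$severe
  u_rx_sev <- if (!is.null(sv$rx_per_user)) cost_mean(sv$rx_per_user, cpi) else u_rx
  u_hcp_sev <- if (!is.null(sv$hcp_visit)) cost_mean(sv$hcp_visit, cpi) else u_hcp

  tier_sum <- function(tier, field) {
    sum(map_dbl(ill_present, function(ill) {
      n <- if (tier == "mild") mild_ill[[ill]] else mod_ill[[ill]]
      n * dist_mean(sev_profile[[ill]][[tier]][[field]])
    }))
  }
  hours_sum <- function(tier) {
    sum(map_dbl(ill_present, function(ill) {
      n <- if (tier == "mild") mild_ill[[ill]] else mod_ill[[ill]]
      n * dist_mean(sev_profile[[ill]][[tier]]$p_work_loss) *
        dist_mean(sev_profile[[ill]][[tier]]$lost_hours)
    }))
  }

  mild <- c(otc = tier_sum("mild", "p_otc") * u_otc,
            rx = tier_sum("mild", "p_rx") * u_rx,
            hcp = 0, ed = 0, hospital = 0, sequelae = 0,
            productivity = hours_sum("mild") * u_wage, death_vsl = 0)
  moderate <- c(otc = tier_sum("moderate", "p_otc") * u_otc,
                rx = tier_sum("moderate", "p_rx") * u_rx,
                hcp = tier_sum("moderate", "p_hcp") * u_hcp,
                ed = tier_sum("moderate", "p_ed") * u_ed,
                hospital = 0, sequelae = 0,
                productivity = hours_sum("moderate") * u_wage, death_vsl = 0)
  H <- sum(hosp)
  severe <- c(otc = H * dist_mean(sv$p_otc) * u_otc,
              rx = H * dist_mean(sv$p_rx) * u_rx_sev,
              hcp = H * dist_mean(sv$p_hcp) * u_hcp_sev,
              ed = H * dist_mean(sv$p_ed) * u_ed,
              hospital = hospital_cost, sequelae = seq_cost,
              productivity = H * dist_mean(sv$p_work_loss) *
                dist_mean(sv$lost_hours) * u_wage,
              death_vsl = sum(deaths) * u_vsl)
  for (tier in c("mild", "moderate", "severe")) {
    v <- get(tier)
    for (comp in names(v)) add(paste0("cost.", tier, ".", comp), v[[comp]])
    add(paste0("cost.", tier, ".total"), sum(v))
  }
  add("grand_total", sum(mild) + sum(moderate) + sum(severe))
  bind_rows(cells)
}

#' Monte Carlo means and standard errors for every truth cell
#'
#' Extracts, from a simulation run with `keep_draws = TRUE`, the empirical
#' mean and Monte Carlo standard error of every cell tabulated by
#' [analytic_expectation()], under the same cell names -- the two tables
#' joined on `cell` give a direct engine-vs-oracle comparison.
#'
#' @param sim A `burden_sim` run with `keep_draws = TRUE`.
#' @return A tibble with columns `cell`, `mc_mean`, `mc_se`.
#' @export
mc_expectation_cells <- function(sim) {
  stopifnot(inherits(sim, "burden_sim"))
  if (is.null(sim$full_draws)) {
    abort("run the simulation with keep_draws = TRUE", class = "aquaburden_error")
  }
  mse <- function(x) tibble(mc_mean = mean(x),
                            mc_se = stats::sd(x) / sqrt(length(x)))
  cell_of <- function(df, cell, value) {
    df |>
      group_by(cell = {{ cell }}) |>
      summarise(out = mse({{ value }}), .groups = "drop") |>
      tidyr::unpack("out")
  }
  per_draw_cases <- sim$draws$cases_by_illness |>
    group_by(.data$draw) |>
    summarise(total = sum(.data$total_cases), mild = sum(.data$mild_cases),
              moderate = sum(.data$moderate_cases), .groups = "drop")
  bind_rows(
    cell_of(sim$full_draws$exposure, paste0("person_days.", .data$activity),
            .data$person_days),
    mse(sim$draws$total_events) |> mutate(cell = "total_events"),
    cell_of(sim$full_draws$caseloads,
            paste0("cases.", .data$activity, ".", .data$illness),
            .data$total_cases),
    cell_of(sim$draws$cases_by_illness, paste0("cases_total.", .data$illness),
            .data$total_cases),
    mse(per_draw_cases$total) |> mutate(cell = "cases_total"),
    mse(per_draw_cases$mild) |> mutate(cell = "mild_cases_total"),
    mse(per_draw_cases$moderate) |> mutate(cell = "moderate_cases_total"),
    cell_of(sim$full_draws$severe, paste0("hospitalizations.", .data$pathogen),
            .data$hospitalizations),
    cell_of(sim$full_draws$severe, paste0("deaths.", .data$pathogen),
            .data$deaths),
    mse(sim$draws$severe_totals$hospitalizations) |>
      mutate(cell = "hospitalizations"),
    mse(sim$draws$severe_totals$deaths) |> mutate(cell = "deaths"),
    sim$draws$tier_costs |>
      tidyr::pivot_longer(all_of(c(cost_components, "total")),
                          names_to = "component", values_to = "value") |>
      cell_of(paste0("cost.", .data$tier, ".", .data$component), .data$value),
    mse(sim$draws$grand_total) |> mutate(cell = "grand_total")
  ) |>
    select("cell", "mc_mean", "mc_se")
}

runif1 <- function(min, max) stats::runif(1, min, max)

synth_spec <- function(mean, rel_sd, family, lower = 0, upper = Inf) {
  switch(family,
    point = list(family = "point", value = mean),
    normal = list(family = "normal", mean = mean, sd = max(mean * rel_sd, 1e-9),
                  lower = lower, upper = upper),
    uniform = list(family = "uniform", min = mean * (1 - rel_sd * 1.7),
                   max = mean * (1 + rel_sd * 1.7)),
    pert = list(family = "pert", min = mean * (1 - rel_sd * 2.4), mode = mean,
                max = mean * (1 + rel_sd * 2.4)),
    triangular = list(family = "triangular", min = mean * (1 - rel_sd * 2.4),
                      mode = mean, max = mean * (1 + rel_sd * 2.4)),
    lognormal = list(family = "lognormal", meanlog = log(mean) - rel_sd^2 / 2,
                     sdlog = rel_sd)
  )
}

#' Generate a random, fully specified scenario with known ground truth
#'
#' Draws a synthetic parameter book -- activities, illness risks, severity
#' and utilization profiles, pathogen records, unit costs -- from documented
#' realistic ranges (participation 1-50%, implied attributable risks
#' -0.01 to 0.05, community multipliers in {1, 1.1, 25.5}, severity
#' fractions up to 0.3), mixing distribution families so every sampler is
#' exercised. The result validates against the scenario schema and carries
#' the closed-form truth table from [analytic_expectation()].
#'
#' @param seed Integer; the generator is deterministic in it.
#' @param n_activities,n_illnesses,n_pathogens Scenario shape
#'   (`n_illnesses` at most 5, the number of sporadic illness types).
#' @return A `synthetic_scenario`: a list with `$scenario` (a validated
#'   `scenario_config`) and `$truth` (a tibble of expected output cells).
#' @examples
#' synth <- generate_scenario(1, n_activities = 2, n_illnesses = 2,
#'                            n_pathogens = 1)
#' head(synth$truth)
#' @export
generate_scenario <- function(seed, n_activities = 6, n_illnesses = 5,
                              n_pathogens = 8) {
  stopifnot(n_activities >= 1, n_illnesses >= 1, n_pathogens >= 1,
            n_illnesses <= length(illness_types))
  set.seed(seed)
  fams <- c("point", "normal", "uniform", "pert", "triangular")
  ill <- illness_types[seq_len(n_illnesses)]

  activities <- lapply(seq_len(n_activities), function(i) {
    list(name = paste0("activity_", i),
         participation_over16 = synth_spec(runif1(0.01, 0.5), 0.03,
                                           sample(fams, 1), upper = 1),
         under16_share = synth_spec(runif1(0.01, 0.8), 0.03,
                                    sample(fams, 1), upper = 1),
         mean_days_per_year = synth_spec(runif1(2, 15), 0.05, sample(fams, 1)))
  })

  risks <- list()
  for (i in seq_len(n_activities)) {
    picked <- which(runif(n_illnesses) < 0.7)
    if (i == 1 && length(picked) == 0) picked <- 1L
    for (j in picked) {
      p_un <- runif1(0.01, 0.1)
      ar <- runif1(-0.01, 0.05)
      risks[[length(risks) + 1]] <- list(
        activity = paste0("activity_", i), illness = ill[j],
        p_exposed = synth_spec(max(p_un + ar, 0.001), 0.08, "normal", upper = 1),
        p_unexposed = synth_spec(p_un, 0.08, sample(c("normal", "uniform"), 1),
                                 upper = 1))
    }
  }

  severity <- lapply(ill, function(nm) {
    util <- function() list(
      p_otc = synth_spec(runif1(0.1, 0.8), 0.05, sample(fams, 1), upper = 1),
      p_rx = synth_spec(runif1(0.02, 0.5), 0.05, sample(fams, 1), upper = 1),
      p_work_loss = synth_spec(runif1(0.1, 0.8), 0.05, sample(fams, 1),
                               upper = 1),
      lost_hours = synth_spec(runif1(0.5, 16), 0.1, sample(fams, 1)))
    m <- util()
    mo <- util()
    mo$p_hcp <- synth_spec(runif1(0.3, 0.85), 0.05, sample(fams, 1), upper = 1)
    mo$p_ed <- synth_spec(runif1(0.05, 0.3), 0.05, sample(fams, 1), upper = 1)
    list(illness = nm,
         moderate_fraction = synth_spec(runif1(0.02, 0.3), 0.08,
                                        sample(fams, 1), upper = 1),
         mild = m, moderate = mo)
  })

  pathogens <- lapply(seq_len(n_pathogens), function(i) {
    out <- list(
      name = paste0("pathogen_", i),
      observed_cases = round(runif1(1, 100)),
      community_multiplier = sample(c(1, 1.1, 25.5), 1),
      severe_correction = 2,
      hosp_fraction = synth_spec(runif1(0.05, 0.3), 0.3, "lognormal"),
      death_fraction = synth_spec(runif1(0.001, 0.05), 0.4, "lognormal"),
      hosp_cost = synth_spec(runif1(4000, 12000), 0.2, "lognormal"))
    if (runif(1) < 0.5) {
      out$sequelae <- list(list(
        name = paste0("sequela_", i),
        probability = synth_spec(runif1(0.001, 0.05), 0.2, "normal", upper = 1),
        excess_cost = synth_spec(runif1(1e4, 3e5), 0.25, "lognormal")))
    }
    out
  })

  costs <- list(
    otc_per_user = synth_spec(runif1(2, 10), 0.1, "pert"),
    rx_per_user = synth_spec(runif1(15, 60), 0.1, "normal"),
    hcp_visit = list(family = "empirical",
                     values = round(runif(12, 50, 150), 2)),
    ed_visit = synth_spec(runif1(300, 1000), 0.12, "uniform"),
    wage_per_hour = synth_spec(runif1(15, 25), 0.05, "triangular"),
    vsl = synth_spec(runif1(5e6, 9e6), 0.3, "lognormal"),
    severe = list(
      p_otc = synth_spec(runif1(0.3, 0.85), 0.05, sample(fams, 1), upper = 1),
      p_rx = synth_spec(runif1(0.3, 0.85), 0.05, sample(fams, 1), upper = 1),
      p_hcp = synth_spec(runif1(0.3, 0.85), 0.05, sample(fams, 1), upper = 1),
      p_ed = synth_spec(runif1(0.1, 0.5), 0.05, sample(fams, 1), upper = 1),
      p_work_loss = synth_spec(runif1(0.5, 1), 0.04, "normal", upper = 1),
      lost_hours = synth_spec(runif1(8, 40), 0.1, sample(fams, 1)),
      rx_per_user = synth_spec(runif1(20, 60), 0.1, "normal"),
      hcp_visit = synth_spec(runif1(100, 300), 0.1, "normal")),
    cpi_factors = list(
      list(year = 2007, series = "medical_commodities", factor = 1),
      list(year = 2007, series = "medical_services", factor = 1),
      list(year = 2007, series = "wages", factor = 1))
  )

  raw <- list(
    name = paste0("synthetic_", seed),
    population = list(reference_year = 2007,
                      adult_population = round(runif1(5e7, 3e8)),
                      child_population = round(runif1(2e7, 8e7))),
    activities = activities, risks = risks, severity = severity,
    pathogens = pathogens, costs = costs,
    options = list(truncate_negative_ar = FALSE, n_iterations = 1000,
                   seed = seed + 1)
  )
  scenario <- build_scenario(raw)
  structure(list(scenario = scenario, truth = analytic_expectation(scenario)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ", x$scenario$name, ": ",
      length(x$scenario$activities), " activities, ",
      length(unique(map_chr(x$scenario$risks, "illness"))), " illness types, ",
      length(x$scenario$pathogens), " pathogens; ",
      nrow(x$truth), " truth cells\n", sep = "")
  invisible(x)
}
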