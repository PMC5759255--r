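# Monte Carlo engine: one global random stream, consumed in a fixed
# parameter order (activities, then illness risks, then severity profiles,
# then pathogens and their sequelae, then unit costs; config order within
# each block, n draws per parameter). Clamped sampling never consumes a
# variable number of deviates, so (scenario, n, seed) fully determines every
# draw.

sample_cost <- function(spec, n, cpi) {
  x <- sample_dist(spec, n)
  if (!is.null(spec$source_year)) {
    x <- inflation_adjust(x, spec$source_year, spec$series, cpi)
  }
  x
}

draw_parameters <- function(scenario, n) {
  cpi <- scenario$costs$cpi_factors
  activities <- map_dfr(scenario$activities, function(a) {
    tibble(activity = a$name, draw = seq_len(n),
           participation = sample_dist(a$participation_over16, n),
           under16_share = sample_dist(a$under16_share, n),
           mean_days = sample_dist(a$mean_days_per_year, n))
  })
  risks <- map_dfr(scenario$risks, function(r) {
    tibble(activity = r$activity, illness = r$illness, draw = seq_len(n),
           p_exposed = sample_dist(r$p_exposed, n),
           p_unexposed = sample_dist(r$p_unexposed, n))
  })
  severity <- map_dfr(scenario$severity, function(s) {
    tibble(illness = s$illness, draw = seq_len(n),
           moderate_fraction = sample_dist(s$moderate_fraction, n),
           mild_p_otc = sample_dist(s$mild$p_otc, n),
           mild_p_rx = sample_dist(s$mild$p_rx, n),
           mild_p_work_loss = sample_dist(s$mild$p_work_loss, n),
           mild_lost_hours = sample_dist(s$mild$lost_hours, n),
           mod_p_otc = sample_dist(s$moderate$p_otc, n),
           mod_p_rx = sample_dist(s$moderate$p_rx, n),
           mod_p_hcp = sample_dist(s$moderate$p_hcp, n),
           mod_p_ed = sample_dist(s$moderate$p_ed, n),
           mod_p_work_loss = sample_dist(s$moderate$p_work_loss, n),
           mod_lost_hours = sample_dist(s$moderate$lost_hours, n))
  })
  pathogens <- map_dfr(scenario$pathogens, function(p) {
    tibble(pathogen = p$name, draw = seq_len(n),
           observed_cases = p$observed_cases,
           community_multiplier = p$community_multiplier,
           severe_correction = p$severe_correction,
           hosp_fraction = sample_dist(p$hosp_fraction, n),
           death_fraction = sample_dist(p$death_fraction, n),
           hosp_cost = sample_cost(p$hosp_cost, n, cpi))
  })
  sequelae <- map_dfr(scenario$pathogens, function(p) {
    map_dfr(p$sequelae, function(sq) {
      tibble(pathogen = p$name, sequela = sq$name, draw = seq_len(n),
             probability = sample_dist(sq$probability, n),
             excess_cost = sample_cost(sq$excess_cost, n, cpi))
    })
  })
  co <- scenario$costs
  sv <- co$severe
  costs <- tibble(
    draw = seq_len(n),
    otc = sample_cost(co$otc_per_user, n, cpi),
    rx = sample_cost(co$rx_per_user, n, cpi),
    hcp = sample_cost(co$hcp_visit, n, cpi),
    ed = sample_cost(co$ed_visit, n, cpi),
    wage = sample_cost(co$wage_per_hour, n, cpi),
    vsl = sample_cost(co$vsl, n, cpi),
    sev_p_otc = sample_dist(sv$p_otc, n),
    sev_p_rx = sample_dist(sv$p_rx, n),
    sev_p_hcp = sample_dist(sv$p_hcp, n),
    sev_p_ed = sample_dist(sv$p_ed, n),
    sev_p_work_loss = sample_dist(sv$p_work_loss, n),
    sev_lost_hours = sample_dist(sv$lost_hours, n)
  )
  costs$sev_rx_unit <- if (!is.null(sv$rx_per_user)) {
    sample_cost(sv$rx_per_user, n, cpi)
  } else costs$rx
  costs$sev_hcp_unit <- if (!is.null(sv$hcp_visit)) {
    sample_cost(sv$hcp_visit, n, cpi)
  } else costs$hcp
  list(activities = activities, risks = risks, severity = severity,
       pathogens = pathogens, sequelae = sequelae, costs = costs)
}

#' Per-tier costs from sampled aggregates
#'
#' Assembles one severity tier's cost breakdown from a case (or
#' hospitalization) count, utilization probabilities, and unit costs,
#' applying the tier composition rule of [cost_breakdown()]. For the severe
#' tier `n_cases` is the hospitalization count and the hospitalization,
#' sequelae, and mortality terms are supplied directly.
#'
#' @param tier `"mild"`, `"moderate"` or `"severe"`.
#' @param n_cases Cases (mild/moderate) or hospitalizations (severe) per
#'   year. Vectorized.
#' @param utilization List with `p_otc`, `p_rx`, `p_work_loss`, `lost_hours`
#'   and, for moderate/severe, `p_hcp`, `p_ed`.
#' @param unit_costs List with `otc`, `rx`, `hcp`, `ed`, `wage`, `vsl`
#'   (dollars).
#' @param hospital,sequelae Severe-tier hospitalization and sequelae costs,
#'   dollars per year.
#' @param deaths Severe-tier deaths per year (costed at `unit_costs$vsl`).
#' @return A [cost_breakdown()] tibble.
#' @export
severity_cost <- function(tier, n_cases, utilization, unit_costs,
                          hospital = 0, sequelae = 0, deaths = 0) {
  u <- utilization
  uc <- unit_costs
  zero <- tier_zero_components[[tier]]
  cost_breakdown(
    tier,
    otc = component_cost(n_cases, u$p_otc, uc$otc),
    rx = component_cost(n_cases, u$p_rx, uc$rx),
    hcp = if ("hcp" %in% zero) 0 else component_cost(n_cases, u$p_hcp, uc$hcp),
    ed = if ("ed" %in% zero) 0 else component_cost(n_cases, u$p_ed, uc$ed),
    hospital = if ("hospital" %in% zero) 0 else hospital,
    sequelae = if ("sequelae" %in% zero) 0 else sequelae,
    productivity = productivity_cost(n_cases, u$p_work_loss, u$lost_hours,
                                     uc$wage),
    death_vsl = if ("death_vsl" %in% zero) 0 else mortality_cost(deaths, uc$vsl)
  )
}

compute_tier_costs <- function(caseloads, severity_draws, severe_draws,
                               sequelae_draws, cost_draws) {
  util <- caseloads |>
    left_join(severity_draws, by = intersect(c("illness", "draw"),
                                             names(severity_draws))) |>
    mutate(
      m_otc = .data$mild_cases * .data$mild_p_otc,
      m_rx = .data$mild_cases * .data$mild_p_rx,
      m_hours = .data$mild_cases * .data$mild_p_work_loss * .data$mild_lost_hours,
      o_otc = .data$moderate_cases * .data$mod_p_otc,
      o_rx = .data$moderate_cases * .data$mod_p_rx,
      o_hcp = .data$moderate_cases * .data$mod_p_hcp,
      o_ed = .data$moderate_cases * .data$mod_p_ed,
      o_hours = .data$moderate_cases * .data$mod_p_work_loss * .data$mod_lost_hours
    ) |>
    group_by(draw = .data$draw) |>
    summarise(across(all_of(c("mild_cases", "moderate_cases", "m_otc", "m_rx",
                              "m_hours", "o_otc", "o_rx", "o_hcp", "o_ed",
                              "o_hours")), sum), .groups = "drop")

  sev <- severe_draws |>
    mutate(hosp_dollars = .data$hospitalizations * .data$hosp_cost) |>
    group_by(draw = .data$draw) |>
    summarise(hospitalizations = sum(.data$hospitalizations),
              deaths = sum(.data$deaths),
              hospital = sum(.data$hosp_dollars), .groups = "drop")

  seq_cost <- if (nrow(sequelae_draws) > 0) {
    sequelae_draws |>
      left_join(select(severe_draws, "pathogen", "draw", "hospitalizations"),
                by = c("pathogen", "draw")) |>
      group_by(draw = .data$draw) |>
      summarise(sequelae = sum(.data$hospitalizations * .data$probability *
                                 .data$excess_cost), .groups = "drop")
  } else {
    tibble(draw = sev$draw, sequelae = 0)
  }

  all <- util |>
    left_join(sev, by = "draw") |>
    left_join(seq_cost, by = "draw") |>
    left_join(cost_draws, by = "draw")

  mild <- cost_breakdown("mild",
    otc = all$m_otc * all$otc,
    rx = all$m_rx * all$rx,
    productivity = all$m_hours * all$wage)
  mild$draw <- all$draw
  mild$n_cases <- all$mild_cases

  moderate <- cost_breakdown("moderate",
    otc = all$o_otc * all$otc,
    rx = all$o_rx * all$rx,
    hcp = all$o_hcp * all$hcp,
    ed = all$o_ed * all$ed,
    productivity = all$o_hours * all$wage)
  moderate$draw <- all$draw
  moderate$n_cases <- all$moderate_cases

  severe <- cost_breakdown("severe",
    otc = all$hospitalizations * all$sev_p_otc * all$otc,
    rx = all$hospitalizations * all$sev_p_rx * all$sev_rx_unit,
    hcp = all$hospitalizations * all$sev_p_hcp * all$sev_hcp_unit,
    ed = all$hospitalizations * all$sev_p_ed * all$ed,
    hospital = all$hospital,
    sequelae = all$sequelae,
    productivity = all$hospitalizations * all$sev_p_work_loss *
      all$sev_lost_hours * all$wage,
    death_vsl = all$deaths * all$vsl)
  severe$draw <- all$draw
  severe$n_cases <- all$hospitalizations + all$deaths

  tier_costs <- bind_rows(mild, moderate, severe) |>
    mutate(per_case = ifelse(.data$n_cases > 0, .data$total / .data$n_cases,
                             NA_real_)) |>
    arrange(.data$draw, match(.data$tier, c("mild", "moderate", "severe")))
  list(tier_costs = tier_costs,
       severe_totals = select(sev, "draw", "hospitalizations", "deaths"))
}

#' Mean and central-90% interval of simulated values
#'
#' The central 90% of values (C90) is the 5th-95th percentile interval of
#' the Monte Carlo draws, computed by linear interpolation between order
#' statistics (the default, type-7 quantile convention). Constant input
#' collapses to `mean = p5 = p95`.
#'
#' @param values Numeric draws (non-empty).
#' @param na_rm Drop `NA` draws before summarizing.
#' @return A tibble with `mean`, `p5`, `p95`, `n_draws`.
#' @examples
#' summarize_c90(1:100) # mean 50.5, p5 5.95, p95 95.05
#' @export
summarize_c90 <- function(values, na_rm = FALSE) {
  if (na_rm) values <- values[!is.na(values)]
  if (length(values) == 0) abort("no draws", class = "aquaburden_no_draws")
  q <- quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  tibble(mean = mean(values), p5 = q[1], p95 = q[2], n_draws = length(values))
}

c90_by <- function(df, value, ..., na_rm = FALSE) {
  df |>
    group_by(...) |>
    summarise(cell = summarize_c90({{ value }}, na_rm = na_rm),
              .groups = "drop") |>
    tidyr::unpack("cell")
}

#' Run the full burden-and-cost Monte Carlo simulation
#'
#' Draws every scenario parameter `n_iterations` times from one seeded
#' random stream (fixed parameter order; see Details), pushes each draw
#' through the exposure, sporadic-illness, severe-illness and cost stages,
#' and summarizes every output as mean with central-90% interval.
#'
#' @details
#' Draw order is: per activity (config order) participation, under-16 share,
#' mean days; per illness risk, exposed then unexposed probability; per
#' severity profile, moderate fraction then mild and moderate utilization;
#' per pathogen, hospitalization fraction, death fraction, hospitalization
#' cost, then its sequelae; finally shared unit costs and severe-tier
#' utilization. Identical `(scenario, n_iterations, seed)` therefore gives
#' bit-identical draws.
#'
#' @param scenario A `scenario_config` (see [read_scenario()],
#'   [us2007_scenario()], [generate_scenario()]).
#' @param n_iterations Number of Monte Carlo iterations (default: the
#'   scenario's `options.n_iterations`).
#' @param seed Integer seed (default: the scenario's `options.seed`).
#' @param truncate_negative_ar Floor negative attributable-risk draws at
#'   zero (default: the scenario's `options.truncate_negative_ar`).
#' @param keep_draws Also retain the full per-draw parameter and caseload
#'   tables (memory-heavy at large `n_iterations`; meant for diagnostics and
#'   property tests).
#' @return A `burden_sim` object: summary tables (`$tables$exposure`,
#'   `$tables$cases`, `$tables$severe`, `$tables$costs`, `$tables$per_case`,
#'   `$tables$grand_total`) and per-draw aggregates (`$draws`). Use
#'   [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' sc <- us2007_scenario()
#' sim <- run_simulation(sc, n_iterations = 200, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(scenario, n_iterations = NULL, seed = NULL,
                           truncate_negative_ar = NULL, keep_draws = FALSE) {
  scenario <- as_scenario_config(scenario)
  n <- n_iterations %||% scenario$options$n_iterations
  seed <- seed %||% scenario$options$seed
  trunc_ar <- truncate_negative_ar %||% scenario$options$truncate_negative_ar
  if (n < 1) bad_param("n_iterations", "must be >= 1")

  set.seed(seed)
  params <- draw_parameters(scenario, n)

  exposure <- compute_exposure(params$activities, scenario$population)
  caseloads <- compute_caseloads(exposure, params$risks, params$severity,
                                 truncate_negative_ar = trunc_ar)
  severe_draws <- compute_severe(params$pathogens)
  tc <- compute_tier_costs(caseloads, params$severity, severe_draws,
                           params$sequelae, params$costs)

  total_events_draws <- exposure |>
    group_by(.data$draw) |>
    summarise(total = sum(.data$person_days), .groups = "drop") |>
    pull(.data$total)

  cases_by_illness <- caseloads |>
    group_by(.data$draw, .data$illness) |>
    summarise(total_cases = sum(.data$total_cases),
              mild_cases = sum(.data$mild_cases),
              moderate_cases = sum(.data$moderate_cases), .groups = "drop")

  grand_total <- tc$tier_costs |>
    group_by(.data$draw) |>
    summarise(total = sum(.data$total), .groups = "drop") |>
    pull(.data$total)

  tables <- list(
    exposure = bind_rows(
      c90_by(exposure |>
               tidyr::pivot_longer(c("recreators_over16", "recreators_under16",
                                     "person_days"),
                                   names_to = "quantity", values_to = "value"),
             .data$value, .data$activity, .data$quantity),
      summarize_c90(total_events_draws) |>
        mutate(activity = "total", quantity = "person_days") |>
        select("activity", "quantity", "mean", "p5", "p95", "n_draws")
    ),
    cases = bind_rows(
      c90_by(caseloads, .data$total_cases, .data$activity, .data$illness),
      c90_by(cases_by_illness, .data$total_cases, .data$illness) |>
        mutate(activity = "total") |>
        select("activity", "illness", "mean", "p5", "p95", "n_draws")
    ),
    severe = bind_rows(
      c90_by(severe_draws |>
               tidyr::pivot_longer(c("community_cases", "hospitalizations",
                                     "deaths"),
                                   names_to = "outcome", values_to = "value"),
             .data$value, .data$pathogen, .data$outcome),
      c90_by(tc$severe_totals |>
               tidyr::pivot_longer(c("hospitalizations", "deaths"),
                                   names_to = "outcome", values_to = "value"),
             .data$value, .data$outcome) |>
        mutate(pathogen = "total") |>
        select("pathogen", "outcome", "mean", "p5", "p95", "n_draws")
    ),
    costs = c90_by(tc$tier_costs |>
                     tidyr::pivot_longer(all_of(c(cost_components, "total")),
                                         names_to = "component",
                                         values_to = "value"),
                   .data$value, .data$tier, .data$component),
    per_case = c90_by(tc$tier_costs, .data$per_case, .data$tier, na_rm = TRUE),
    grand_total = summarize_c90(grand_total)
  )

  structure(
    list(
      scenario = scenario, n_iterations = n, seed = seed,
      truncate_negative_ar = trunc_ar,
      tables = tables,
      draws = list(
        total_events = total_events_draws,
        cases_by_illness = cases_by_illness,
        tier_costs = tc$tier_costs,
        severe_totals = tc$severe_totals,
        grand_total = grand_total
      ),
      full_draws = if (keep_draws) {
        list(params = params, exposure = exposure, caseloads = caseloads,
             severe = severe_draws)
      }
    ),
    class = "burden_sim"
  )
}

#' Collapse every scenario distribution to its mean
#'
#' @param scenario A `scenario_config`.
#' @return The same scenario with every distribution replaced by a point
#'   mass at its analytic mean (clamping accounted for).
#' @export
as_point_scenario <- function(scenario) {
  scenario <- as_scenario_config(scenario)
  pointify <- function(x) {
    if (inherits(x, "dist_spec")) {
      return(dist_spec("point", value = dist_mean(x),
                       source_year = x$source_year, series = x$series))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, pointify))
    x
  }
  structure(pointify(unclass(scenario)), class = "scenario_config")
}

#' Deterministic point-mass evaluation of a scenario
#'
#' Runs the full pipeline once with every distribution collapsed to its
#' mean. Because all parameters enter through products and sums of
#' independent draws, this single evaluation equals the analytic expectation
#' of every product-chain output cell and is the oracle the Monte Carlo
#' summaries are tested against.
#'
#' @param scenario A `scenario_config`.
#' @return A `burden_sim` with `n_iterations = 1`.
#' @examples
#' pt <- point_estimate(us2007_scenario())
#' pt$tables$exposure[pt$tables$exposure$activity == "total", ]
#' @export
point_estimate <- function(scenario) {
  run_simulation(as_point_scenario(scenario), n_iterations = 1, seed = 0,
                 keep_draws = TRUE)
}

#' Write simulation report files
#'
#' Writes the exposure, caseload, and cost summary tables as CSV, the full
#' summary set as JSON, and a plain-text run manifest (scenario name, seed,
#' iteration count, configuration hash) into `dir` (created if needed).
#'
#' @param sim A `burden_sim`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "burden_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    exposure = file.path(dir, "table1_exposure.csv"),
    cases = file.path(dir, "table3_cases.csv"),
    costs = file.path(dir, "table4_costs.csv"),
    summary = file.path(dir, "summary.json"),
    manifest = file.path(dir, "run_manifest.txt")
  )
  write.csv(sim$tables$exposure, paths[["exposure"]], row.names = FALSE)
  write.csv(sim$tables$cases, paths[["cases"]], row.names = FALSE)
  write.csv(sim$tables$costs, paths[["costs"]], row.names = FALSE)
  jsonlite::write_json(sim$tables, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  writeLines(c(
    paste0("scenario: ", sim$scenario$name),
    paste0("n_iterations: ", sim$n_iterations),
    paste0("seed: ", sim$seed),
    paste0("truncate_negative_ar: ", sim$truncate_negative_ar),
    paste0("config_hash: ", rlang::hash(sim$scenario)),
    paste0("aquaburden_version: ",
           as.character(utils::packageVersion("aquaburden")))
  ), paths[["manifest"]])
  invisible(paths)
}
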