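#' @title Scenario configuration: the parameter book
#'
#' @description
#' A `scenario_config` holds everything the pipeline needs: census population
#' bases, per-activity participation and days-per-recreator distributions,
#' per-(activity, illness) exposed/unexposed illness probabilities, severity
#' and healthcare-utilization profiles, pathogen surveillance records with
#' underreporting multipliers, and unit-cost distributions with
#' consumer-price-index factors. Scenarios are stored as YAML (canonical) or
#' JSON; [read_scenario()] validates every invariant on load and rejects
#' unknown keys, so downstream code can trust the object.
#'
#' @name scenario_config
NULL

illness_types <- c("agi", "respiratory", "eye", "ear", "skin")

malformed <- function(msg) {
  abort(paste0("malformed config: ", msg), class = "aquaburden_malformed_config")
}

check_keys <- function(x, required, optional, where) {
  if (!is.list(x)) malformed(paste0(where, " must be a mapping"))
  nms <- names(x)
  if (is.null(nms) || any(nms == "")) malformed(paste0(where, " has unnamed entries"))
  missing <- setdiff(required, nms)
  if (length(missing) > 0) {
    malformed(paste0(where, " is missing key(s): ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(nms, c(required, optional))
  if (length(extra) > 0) {
    malformed(paste0(where, " has unknown key(s): ", paste(extra, collapse = ", ")))
  }
  invisible(x)
}

# scalars are shorthand for point masses; maps must carry a `family` key
as_dist_spec <- function(x, field) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    return(dist_spec("point", value = x))
  }
  if (is.list(x) && !is.null(x$family)) {
    meta <- c("family", "lower", "upper", "source_year", "series")
    params <- x[setdiff(names(x), meta)]
    if ("values" %in% names(params)) params$values <- unlist(params$values)
    spec <- tryCatch(
      do.call(dist_spec, c(list(family = x$family), params,
                           list(lower = x$lower %||% -Inf, upper = x$upper %||% Inf,
                                source_year = x$source_year, series = x$series))),
      aquaburden_invalid_parameter = function(e) {
        bad_param(field, conditionMessage(e))
      }
    )
    return(spec)
  }
  bad_param(field, "expected a number or a distribution mapping with a 'family' key")
}

# proportions are clamped into [0, 1] after sampling (see vignette); here we
# impose the clamp and reject means outside the unit interval
as_proportion_spec <- function(x, field) {
  spec <- as_dist_spec(x, field)
  if (spec$family %in% c("normal", "truncated_normal", "lognormal", "empirical")) {
    spec$lower <- max(spec$lower, 0)
    spec$upper <- min(spec$upper, 1)
    if (spec$family == "normal") spec$family <- "truncated_normal"
  } else {
    support <- switch(spec$family,
      point = c(spec$params$value, spec$params$value),
      uniform = c(spec$params$min, spec$params$max),
      triangular = ,
      pert = c(spec$params$min, spec$params$max)
    )
    if (support[1] < 0 || support[2] > 1) {
      bad_param(field, "support must lie in [0, 1] for a proportion")
    }
  }
  m <- dist_mean(spec)
  if (m < 0 || m > 1) bad_param(field, "mean proportion outside [0, 1]")
  spec
}

as_nonneg_spec <- function(x, field) {
  spec <- as_dist_spec(x, field)
  if (spec$family %in% c("normal", "truncated_normal")) {
    spec$lower <- max(spec$lower, 0)
  }
  if (dist_mean(spec) < 0) bad_param(field, "mean must be non-negative")
  spec
}

scalar_number <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bad_param(field, "must be a finite number")
  }
  if (x < min) bad_param(field, paste0("must be >= ", min))
  x
}

tier_fields <- list(
  mild = c("p_otc", "p_rx", "p_work_loss", "lost_hours"),
  moderate = c("p_otc", "p_rx", "p_hcp", "p_ed", "p_work_loss", "lost_hours"),
  severe = c("p_otc", "p_rx", "p_hcp", "p_ed", "p_work_loss", "lost_hours")
)

parse_utilization <- function(x, tier, where) {
  check_keys(x, tier_fields[[tier]],
             if (tier == "severe") c("rx_per_user", "hcp_visit") else character(),
             where)
  out <- list()
  for (f in tier_fields[[tier]]) {
    field <- paste0(where, ".", f)
    out[[f]] <- if (f == "lost_hours") as_nonneg_spec(x[[f]], field)
                else as_proportion_spec(x[[f]], field)
  }
  if (tier == "severe") {
    for (f in c("rx_per_user", "hcp_visit")) {
      if (!is.null(x[[f]])) out[[f]] <- as_nonneg_spec(x[[f]], paste0(where, ".", f))
    }
  }
  out
}

build_scenario <- function(raw) {
  if (is.null(raw) || !is.list(raw) || length(raw) == 0) {
    malformed("empty or non-mapping document")
  }
  check_keys(raw, c("population", "activities", "risks", "severity",
                    "pathogens", "costs", "options"),
             "name", "scenario")

  pop <- check_keys(raw$population,
                    c("reference_year", "adult_population", "child_population"),
                    character(), "population")
  population <- list(
    reference_year = scalar_number(pop$reference_year, "population.reference_year"),
    adult_population = scalar_number(pop$adult_population, "population.adult_population"),
    child_population = scalar_number(pop$child_population, "population.child_population")
  )
  if (population$adult_population <= 0) bad_param("population.adult_population", "must be > 0")
  if (population$child_population <= 0) bad_param("population.child_population", "must be > 0")

  if (length(raw$activities) == 0) malformed("at least one activity is required")
  activities <- map(raw$activities, function(a) {
    check_keys(a, c("name", "participation_over16", "under16_share",
                    "mean_days_per_year"), character(), "activities[]")
    w <- paste0("activities.", a$name)
    list(
      name = as.character(a$name),
      participation_over16 = as_proportion_spec(a$participation_over16,
                                                paste0(w, ".participation_over16")),
      under16_share = as_proportion_spec(a$under16_share, paste0(w, ".under16_share")),
      mean_days_per_year = as_nonneg_spec(a$mean_days_per_year,
                                          paste0(w, ".mean_days_per_year"))
    )
  })
  act_names <- map_chr(activities, "name")
  if (anyDuplicated(act_names)) bad_param("activities", "duplicate activity names")

  risks <- map(raw$risks, function(r) {
    check_keys(r, c("activity", "illness", "p_exposed", "p_unexposed"),
               character(), "risks[]")
    w <- paste0("risks.", r$activity, ".", r$illness)
    if (!r$activity %in% act_names) {
      bad_param(paste0(w, ".activity"), "references an undeclared activity")
    }
    if (!r$illness %in% illness_types) {
      bad_param(paste0(w, ".illness"), paste0("must be one of ",
                                              paste(illness_types, collapse = ", ")))
    }
    list(
      activity = as.character(r$activity),
      illness = as.character(r$illness),
      p_exposed = as_proportion_spec(r$p_exposed, paste0(w, ".p_exposed")),
      p_unexposed = as_proportion_spec(r$p_unexposed, paste0(w, ".p_unexposed"))
    )
  })
  risk_keys <- vapply(risks, function(r) paste(r$activity, r$illness), character(1))
  if (anyDuplicated(risk_keys)) bad_param("risks", "duplicate (activity, illness) pair")

  severity <- map(raw$severity, function(s) {
    check_keys(s, c("illness", "moderate_fraction", "mild", "moderate"),
               character(), "severity[]")
    w <- paste0("severity.", s$illness)
    if (!s$illness %in% illness_types) {
      bad_param(paste0(w, ".illness"), "unknown illness type")
    }
    list(
      illness = as.character(s$illness),
      moderate_fraction = as_proportion_spec(s$moderate_fraction,
                                             paste0(w, ".moderate_fraction")),
      mild = parse_utilization(s$mild, "mild", paste0(w, ".mild")),
      moderate = parse_utilization(s$moderate, "moderate", paste0(w, ".moderate"))
    )
  })
  sev_ill <- map_chr(severity, "illness")
  if (anyDuplicated(sev_ill)) bad_param("severity", "duplicate illness profile")
  risk_ill <- unique(map_chr(risks, "illness"))
  if (length(setdiff(risk_ill, sev_ill)) > 0) {
    bad_param("severity", paste0("missing severity profile for: ",
                                 paste(setdiff(risk_ill, sev_ill), collapse = ", ")))
  }

  pathogens <- map(raw$pathogens, function(p) {
    check_keys(p, c("name", "observed_cases", "community_multiplier",
                    "severe_correction", "hosp_fraction", "death_fraction",
                    "hosp_cost"), "sequelae", "pathogens[]")
    w <- paste0("pathogens.", p$name)
    mult <- scalar_number(p$community_multiplier, paste0(w, ".community_multiplier"))
    if (mult < 1) bad_param(paste0(w, ".community_multiplier"), "multiplier must be >= 1")
    corr <- scalar_number(p$severe_correction, paste0(w, ".severe_correction"))
    if (corr < 1) bad_param(paste0(w, ".severe_correction"), "must be >= 1")
    list(
      name = as.character(p$name),
      observed_cases = scalar_number(p$observed_cases, paste0(w, ".observed_cases"), min = 0),
      community_multiplier = mult,
      severe_correction = corr,
      hosp_fraction = as_proportion_spec(p$hosp_fraction, paste0(w, ".hosp_fraction")),
      death_fraction = as_proportion_spec(p$death_fraction, paste0(w, ".death_fraction")),
      hosp_cost = as_nonneg_spec(p$hosp_cost, paste0(w, ".hosp_cost")),
      sequelae = map(p$sequelae %||% list(), function(sq) {
        check_keys(sq, c("name", "probability", "excess_cost"), character(),
                   paste0(w, ".sequelae[]"))
        list(
          name = as.character(sq$name),
          probability = as_proportion_spec(sq$probability,
                                           paste0(w, ".sequelae.", sq$name, ".probability")),
          excess_cost = as_nonneg_spec(sq$excess_cost,
                                       paste0(w, ".sequelae.", sq$name, ".excess_cost"))
        )
      })
    )
  })
  if (anyDuplicated(map_chr(pathogens, "name"))) {
    bad_param("pathogens", "duplicate pathogen names")
  }

  co <- check_keys(raw$costs,
                   c("otc_per_user", "rx_per_user", "hcp_visit", "ed_visit",
                     "wage_per_hour", "vsl", "severe", "cpi_factors"),
                   character(), "costs")
  costs <- list(
    otc_per_user = as_nonneg_spec(co$otc_per_user, "costs.otc_per_user"),
    rx_per_user = as_nonneg_spec(co$rx_per_user, "costs.rx_per_user"),
    hcp_visit = as_nonneg_spec(co$hcp_visit, "costs.hcp_visit"),
    ed_visit = as_nonneg_spec(co$ed_visit, "costs.ed_visit"),
    wage_per_hour = as_nonneg_spec(co$wage_per_hour, "costs.wage_per_hour"),
    vsl = as_nonneg_spec(co$vsl, "costs.vsl"),
    severe = parse_utilization(co$severe, "severe", "costs.severe"),
    cpi_factors = parse_cpi(co$cpi_factors, population$reference_year)
  )

  op <- check_keys(raw$options,
                   c("truncate_negative_ar", "n_iterations", "seed"),
                   character(), "options")
  if (!is.logical(op$truncate_negative_ar) || length(op$truncate_negative_ar) != 1) {
    bad_param("options.truncate_negative_ar", "must be true or false")
  }
  options <- list(
    truncate_negative_ar = op$truncate_negative_ar,
    n_iterations = scalar_number(op$n_iterations, "options.n_iterations", min = 1),
    seed = scalar_number(op$seed, "options.seed")
  )

  structure(
    list(name = raw$name %||% "scenario", population = population,
         activities = activities, risks = risks, severity = severity,
         pathogens = pathogens, costs = costs, options = options),
    class = "scenario_config"
  )
}

parse_cpi <- function(x, reference_year) {
  if (is.null(x) || length(x) == 0) malformed("costs.cpi_factors must be non-empty")
  tbl <- map_dfr(x, function(row) {
    check_keys(row, c("year", "series", "factor"), character(), "costs.cpi_factors[]")
    tibble(year = scalar_number(row$year, "cpi.year"),
           series = as.character(row$series),
           factor = scalar_number(row$factor, "cpi.factor", min = 0))
  })
  if (anyDuplicated(tbl[c("year", "series")])) {
    bad_param("costs.cpi_factors", "duplicate (year, series) entries")
  }
  ref <- tbl$factor[tbl$year == reference_year]
  if (length(ref) > 0 && any(ref != 1)) {
    bad_param("costs.cpi_factors", "reference-year factors must equal 1")
  }
  tbl
}

#' Read and validate a scenario configuration
#'
#' Parses a YAML (canonical) or JSON scenario file into a validated
#' `scenario_config`. All schema invariants are checked on load: proportions
#' must have means in `[0, 1]` (and are clamped there when sampled),
#' multipliers must be at least 1, every illness risk must reference a
#' declared activity, and unknown keys anywhere in the document are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A `scenario_config` object.
#' @seealso [us2007_scenario()] for the packaged 2007 United States scenario,
#'   [write_scenario()] for the inverse operation.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) malformed(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext == "json") {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) malformed(conditionMessage(e))
  )
  build_scenario(raw)
}

#' Coerce a nested list into a validated scenario
#'
#' @param raw A nested list with the same shape as a parsed scenario file.
#' @return A `scenario_config`.
#' @export
as_scenario_config <- function(raw) {
  if (inherits(raw, "scenario_config")) return(raw)
  build_scenario(raw)
}

deflate_spec <- function(spec) {
  out <- c(list(family = spec$family), spec$params)
  if (is.finite(spec$lower)) out$lower <- spec$lower
  if (is.finite(spec$upper)) out$upper <- spec$upper
  if (!is.null(spec$source_year)) out$source_year <- spec$source_year
  if (!is.null(spec$series)) out$series <- spec$series
  out
}

deflate <- function(x) {
  if (inherits(x, "dist_spec")) return(deflate_spec(x))
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])))
  }
  if (is.list(x)) return(lapply(x, deflate))
  x
}

#' Write a scenario configuration to disk
#'
#' Serializes a `scenario_config` to YAML or JSON (chosen by file
#' extension). Reading the file back yields an equal configuration
#' (round-trip property).
#'
#' @param scenario A `scenario_config`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  scenario <- as_scenario_config(scenario)
  raw <- deflate(unclass(scenario))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path, precision = 15)
  }
  invisible(path)
}

#' The packaged 2007 United States scenario
#'
#' Parameter book for the 2007 US national burden estimate: six activities
#' (swimming, kayaking, rowing, canoeing, motor boating, warm-water fishing),
#' five sporadic illness types (AGI, respiratory, eye, ear, skin), and nine
#' pathogens with surveillance counts and underreporting multipliers.
#' Headline participation, risk, and severity parameters follow published
#' national estimates; unit costs and pathogen-specific fractions are
#' documented calibrated reconstructions (see the package vignette and
#' `data-raw/us2007.R`).
#'
#' @return A `scenario_config`.
#' @examples
#' sc <- us2007_scenario()
#' length(sc$activities)
#' @export
us2007_scenario <- function() {
  read_scenario(system.file("extdata", "us2007.yaml", package = "aquaburden",
                            mustWork = TRUE))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, "\n", sep = "")
  cat("  reference year: ", x$population$reference_year,
      "; adults ", format(x$population$adult_population, big.mark = ","),
      "; children ", format(x$population$child_population, big.mark = ","), "\n", sep = "")
  cat("  activities: ", paste(map_chr(x$activities, "name"), collapse = ", "), "\n", sep = "")
  cat("  illness risks: ", length(x$risks), " (activity, illness) pairs\n", sep = "")
  cat("  pathogens: ", paste(map_chr(x$pathogens, "name"), collapse = ", "), "\n", sep = "")
  cat("  options: n_iterations = ", x$options$n_iterations,
      ", seed = ", x$options$seed,
      ", truncate_negative_ar = ", x$options$truncate_negative_ar, "\n", sep = "")
  invisible(x)
}
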