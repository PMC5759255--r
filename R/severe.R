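#' Correct passive surveillance counts for underreporting
#'
#' Passive outbreak surveillance captures only a fraction of community
#' cases. Observed counts are scaled by a pathogen-specific community
#' multiplier: 25.5 for most enteric pathogens (borrowed from foodborne
#' outbreak validation studies), 1.1 for vibriosis (whose single cases are
#' already captured), and 1.0 for *Naegleria fowleri* (nearly always fatal,
#' hence unlikely to go unrecognized).
#'
#' @param observed Cases per year detected by surveillance. Vectorized.
#' @param multiplier Community multiplier, at least 1.
#' @return Estimated community cases per year.
#' @examples
#' adjust_for_underreporting(100, 25.5) # 2550
#' @export
adjust_for_underreporting <- function(observed, multiplier) {
  stopifnot(all(observed >= 0))
  if (any(multiplier < 1)) {
    abort("invalid multiplier: community multiplier must be >= 1",
          class = "aquaburden_invalid_multiplier")
  }
  observed * multiplier
}

#' Hospitalizations and deaths from community case counts
#'
#' Applies pathogen-specific hospitalization and death fractions (among
#' laboratory-confirmed cases) to community case counts, then doubles both
#' outcomes (`severe_correction = 2` by default) because hospitalization and
#' death records themselves underdiagnose pathogen-specific illness.
#'
#' @param community_cases Community cases per year. Vectorized.
#' @param hosp_fraction,death_fraction Probabilities in `[0, 1]`.
#' @param severe_correction Underdiagnosis correction for severe outcomes,
#'   at least 1 (default 2).
#' @return A tibble with columns `community_cases`, `hospitalizations`,
#'   `deaths`.
#' @examples
#' severe_outcomes(1000, 0.05, 0.001) # 100 hospitalizations, 2 deaths
#' @export
severe_outcomes <- function(community_cases, hosp_fraction, death_fraction,
                            severe_correction = 2) {
  stopifnot(all(community_cases >= 0),
            all(hosp_fraction >= 0 & hosp_fraction <= 1),
            all(death_fraction >= 0 & death_fraction <= 1),
            all(severe_correction >= 1))
  tibble(
    community_cases = community_cases,
    hospitalizations = community_cases * hosp_fraction * severe_correction,
    deaths = community_cases * death_fraction * severe_correction
  )
}

#' Total hospitalizations and deaths over pathogens
#'
#' @param outcomes A data frame with `hospitalizations` and `deaths` columns
#'   (one row per pathogen), e.g. from [severe_outcomes()].
#' @return A one-row tibble with summed `hospitalizations` and `deaths`
#'   (zeros for an empty table).
#' @export
aggregate_severe <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    return(tibble(hospitalizations = 0, deaths = 0))
  }
  tibble(hospitalizations = sum(outcomes$hospitalizations),
         deaths = sum(outcomes$deaths))
}

#' Per-pathogen severe outcomes from sampled parameters
#'
#' @param pathogen_draws Tibble with columns `pathogen`, `observed_cases`,
#'   `community_multiplier`, `severe_correction`, `hosp_fraction`,
#'   `death_fraction` (and optionally `draw`).
#' @return The input with `community_cases`, `hospitalizations`, `deaths`
#'   columns added.
#' @export
compute_severe <- function(pathogen_draws) {
  pathogen_draws |>
    mutate(
      community_cases = adjust_for_underreporting(.data$observed_cases,
                                                  .data$community_multiplier),
      hospitalizations = .data$community_cases * .data$hosp_fraction *
        .data$severe_correction,
      deaths = .data$community_cases * .data$death_fraction *
        .data$severe_correction
    )
}

#' Read a pathogen surveillance table from CSV
#'
#' Convenience loader for a plain pathogen table (columns `pathogen`,
#' `observed_cases`, `community_multiplier`, `hosp_fraction`,
#' `death_fraction`, `severe_correction`); point values only. Validated on
#' load.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pathogen_table <- function(path) {
  tbl <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("pathogen", "observed_cases", "community_multiplier",
            "hosp_fraction", "death_fraction", "severe_correction")
  if (!all(need %in% names(tbl))) {
    malformed(paste0("pathogen table must have columns: ",
                     paste(need, collapse = ", ")))
  }
  if (any(tbl$community_multiplier < 1)) {
    abort("invalid multiplier: community multiplier must be >= 1",
          class = "aquaburden_invalid_multiplier")
  }
  if (any(tbl$hosp_fraction < 0 | tbl$hosp_fraction > 1) ||
      any(tbl$death_fraction < 0 | tbl$death_fraction > 1)) {
    bad_param("hosp_fraction/death_fraction", "must be probabilities in [0, 1]")
  }
  tbl
}
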