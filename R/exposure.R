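#' Recreators aged 16 and over for one activity
#'
#' Scales an activity participation proportion by the non-institutionalized
#' census population aged 16 and over.
#'
#' @param participation Proportion of the adult population engaging in the
#'   activity annually (in `[0, 1]`). Vectorized.
#' @param adult_population Census persons aged 16 and over.
#' @return Persons. `recreators_over16(0.237, 233.5e6)` is 55.34 million.
#' @export
recreators_over16 <- function(participation, adult_population) {
  if (any(participation < 0) || any(adult_population < 0)) {
    bad_param("participation/adult_population", "must be non-negative")
  }
  participation * adult_population
}

#' Recreators under 16 for one activity
#'
#' The under-16 recreator count is stored as a share of the under-16 census
#' population (the directly checkable convention); see
#' [recreators_under16_from_ratio()] for the cohort-ratio alternative.
#'
#' @param under16_share Share of the under-16 population engaging in the
#'   activity (in `[0, 1]`). Vectorized.
#' @param child_population Census persons under 16.
#' @return Persons.
#' @export
recreators_under16 <- function(under16_share, child_population) {
  if (any(under16_share < 0) || any(child_population < 0)) {
    bad_param("under16_share/child_population", "must be non-negative")
  }
  under16_share * child_population
}

#' Under-16 recreators from a child-to-adult cohort ratio
#'
#' Cohort studies report the ratio of under-16 to over-16 participants per
#' activity; multiplying that ratio by the adult recreator count is an
#' alternative route to the under-16 count. Provided for sensitivity
#' analysis; the packaged scenario uses [recreators_under16()].
#'
#' @param adult_recreators Persons aged 16 and over engaging in the activity.
#' @param child_adult_ratio Under-16 to over-16 participant ratio.
#' @return Persons under 16.
#' @export
recreators_under16_from_ratio <- function(adult_recreators, child_adult_ratio) {
  if (any(adult_recreators < 0) || any(child_adult_ratio < 0)) {
    bad_param("adult_recreators/child_adult_ratio", "must be non-negative")
  }
  adult_recreators * child_adult_ratio
}

#' Annual recreation events (person-days) for one activity
#'
#' One recreation event is one person-day of one activity: the number of
#' recreators (all ages) times the mean days of that activity per recreator
#' per year.
#'
#' @param recreators_total Persons (all ages). Vectorized.
#' @param mean_days Days per recreator per year.
#' @return Person-days per year.
#' @export
person_days <- function(recreators_total, mean_days) {
  stopifnot(all(recreators_total >= 0), all(mean_days >= 0))
  recreators_total * mean_days
}

#' Total annual recreation events over all activities
#'
#' @param exposures A data frame with a `person_days` column (one row per
#'   activity), as produced by [compute_exposure()].
#' @return Person-days per year, summed over activities. Zero for an empty
#'   table.
#' @export
total_events <- function(exposures) {
  if (is.null(exposures) || nrow(exposures) == 0) return(0)
  stopifnot("person_days" %in% names(exposures))
  sum(exposures$person_days)
}

#' Per-activity exposure from sampled parameters
#'
#' Converts a table of sampled participation proportions, under-16 shares,
#' and days-per-recreator into recreator counts and annual person-days.
#' Used per Monte Carlo draw by [run_simulation()]; can also be called
#' directly on point values.
#'
#' @param params A data frame with columns `activity`, `participation`,
#'   `under16_share`, `mean_days` (and optionally `draw`).
#' @param population A list with `adult_population` and `child_population`
#'   (persons), e.g. `us2007_scenario()$population`.
#' @return The input tibble with `recreators_over16`, `recreators_under16`,
#'   and `person_days` columns added.
#' @examples
#' pop <- list(adult_population = 233.5e6, child_population = 63.3e6)
#' compute_exposure(
#'   tibble::tibble(activity = "fishing", participation = 0.237,
#'                  under16_share = 0.323, mean_days = 14.6),
#'   pop
#' )
#' @export
compute_exposure <- function(params, population) {
  stopifnot(all(c("activity", "participation", "under16_share", "mean_days")
                %in% names(params)))
  params |>
    mutate(
      recreators_over16 = recreators_over16(.data$participation,
                                            population$adult_population),
      recreators_under16 = recreators_under16(.data$under16_share,
                                              population$child_population),
      person_days = person_days(.data$recreators_over16 + .data$recreators_under16,
                                .data$mean_days)
    ) |>
    as_tibble()
}
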