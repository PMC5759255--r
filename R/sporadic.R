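#' Attributable risk of illness per recreation event
#'
#' Risk difference between exposed (water recreators) and unexposed
#' (non-recreator) illness probabilities. Negative differences -- which arise
#' when the sampled unexposed probability exceeds the exposed one -- propagate
#' by default, matching the main analysis; set `truncate_at_zero = TRUE` to
#' floor them at zero (a sensitivity switch that never decreases expected
#' case counts).
#'
#' @param p_exposed,p_unexposed Illness probabilities in `[0, 1]`, over the
#'   same recall window. Vectorized.
#' @param truncate_at_zero Floor negative risk differences at zero.
#' @return Risk difference per recreation event.
#' @examples
#' attributable_risk(0.040, 0.025) # swimming AGI, 0.015
#' attributable_risk(0.02, 0.05, truncate_at_zero = TRUE) # 0
#' @export
attributable_risk <- function(p_exposed, p_unexposed, truncate_at_zero = FALSE) {
  stopifnot(all(p_exposed >= 0 & p_exposed <= 1),
            all(p_unexposed >= 0 & p_unexposed <= 1))
  ar <- p_exposed - p_unexposed
  if (isTRUE(truncate_at_zero)) ar <- pmax(ar, 0)
  ar
}

#' Expected annual cases from events and attributable risk
#'
#' Cases per year are recreation events (person-days) times the attributable
#' risk per event. A negative attributable-risk draw yields a negative case
#' contribution, which is propagated (not floored) unless truncation was
#' requested upstream.
#'
#' @param person_days Recreation events per year (non-negative). Vectorized.
#' @param ar Attributable risk per event (may be negative).
#' @return Cases per year.
#' @export
expected_cases <- function(person_days, ar) {
  stopifnot(all(person_days >= 0))
  person_days * ar
}

#' Split total cases into mild and moderate severity
#'
#' The moderate tier comprises cases that contact a healthcare provider or
#' visit an emergency department; everything else is mild. Mild and moderate
#' always sum to the total.
#'
#' @param total_cases Cases per year. Vectorized.
#' @param moderate_fraction Proportion of cases in the moderate tier.
#' @return A tibble with columns `mild_cases` and `moderate_cases`.
#' @export
split_severity <- function(total_cases, moderate_fraction) {
  stopifnot(all(moderate_fraction >= 0 & moderate_fraction <= 1))
  moderate <- total_cases * moderate_fraction
  tibble(mild_cases = total_cases - moderate, moderate_cases = moderate)
}

#' Overall moderate-severity share of sporadic illness
#'
#' @param caseloads A data frame with `total_cases` and `moderate_cases`
#'   columns (any grouping rows; summed over all of them).
#' @return Proportion of all sporadic cases that are moderate.
#' @export
moderate_share_overall <- function(caseloads) {
  stopifnot(all(c("total_cases", "moderate_cases") %in% names(caseloads)))
  total <- sum(caseloads$total_cases)
  if (total <= 0) abort("no cases", class = "aquaburden_no_cases")
  sum(caseloads$moderate_cases) / total
}

#' Per-(activity, illness) caseloads from sampled parameters
#'
#' Joins sampled exposed/unexposed illness probabilities to per-activity
#' person-days, forms attributable risks and annual case counts, and splits
#' them into mild and moderate tiers. Only declared (activity, illness)
#' pairs appear; pairs with no excess risk are absent and contribute exactly
#' zero cases and zero variance.
#'
#' @param exposure Tibble from [compute_exposure()] (columns `activity`,
#'   `person_days`, optionally `draw`).
#' @param risks Tibble with columns `activity`, `illness`, `p_exposed`,
#'   `p_unexposed` (and `draw` when per-draw).
#' @param severity Tibble with columns `illness`, `moderate_fraction` (and
#'   `draw`).
#' @param truncate_negative_ar Floor negative attributable-risk draws at zero.
#' @return Tibble with one row per activity-illness pair (per draw) and columns
#'   `ar`, `total_cases`, `mild_cases`, `moderate_cases`.
#' @export
compute_caseloads <- function(exposure, risks, severity,
                              truncate_negative_ar = FALSE) {
  by_expo <- intersect(c("activity", "draw"), intersect(names(risks), names(exposure)))
  by_sev <- intersect(c("illness", "draw"), intersect(names(risks), names(severity)))
  risks |>
    left_join(select(exposure, all_of(c(by_expo, "person_days"))), by = by_expo) |>
    left_join(select(severity, all_of(c(by_sev, "moderate_fraction"))), by = by_sev) |>
    mutate(
      ar = attributable_risk(.data$p_exposed, .data$p_unexposed,
                             truncate_at_zero = truncate_negative_ar),
      total_cases = expected_cases(.data$person_days, .data$ar),
      moderate_cases = .data$total_cases * .data$moderate_fraction,
      mild_cases = .data$total_cases - .data$moderate_cases
    ) |>
    select(any_of(c("draw", "activity", "illness", "person_days", "ar",
                    "total_cases", "mild_cases", "moderate_cases")))
}
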