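#' Adjust a cost to reference-year dollars
#'
#' Multiplies an amount by the consumer-price-index factor for its source
#' year and price series (medical commodities for medications, medical
#' services for provider/hospital care, wages for productivity). Factors
#' express conversion *to* the scenario's reference year; the reference year
#' itself has factor 1.
#'
#' @param amount Dollars in `year` terms. Vectorized.
#' @param year Calendar year the amount is quoted in.
#' @param series Price series, e.g. `"medical_commodities"`,
#'   `"medical_services"`, `"wages"`.
#' @param cpi_factors A data frame with columns `year`, `series`, `factor`
#'   (e.g. `us2007_scenario()$costs$cpi_factors`).
#' @return Dollars in reference-year terms.
#' @export
inflation_adjust <- function(amount, year, series, cpi_factors) {
  hit <- cpi_factors$year == year & cpi_factors$series == series
  if (sum(hit) != 1) {
    abort(paste0("unknown CPI key: (", year, ", ", series, ")"),
          class = "aquaburden_unknown_cpi_key")
  }
  amount * cpi_factors$factor[hit]
}

#' Direct cost of one utilization component
#'
#' Cases times the probability of using the resource times its unit cost --
#' the building block for over-the-counter medication, prescription,
#' provider-visit, and emergency-department terms.
#'
#' @param n_cases Cases per year. Vectorized.
#' @param usage_probability Probability a case uses the resource, in `[0, 1]`.
#' @param unit_cost Dollars per user.
#' @return Dollars per year.
#' @export
component_cost <- function(n_cases, usage_probability, unit_cost) {
  stopifnot(all(usage_probability >= 0 & usage_probability <= 1))
  n_cases * usage_probability * unit_cost
}

#' Indirect cost of lost productivity
#'
#' @param n_cases Cases per year. Vectorized.
#' @param p_work_loss Probability a case misses work (or equivalent
#'   activity), in `[0, 1]`.
#' @param lost_hours Mean hours lost per case with work loss.
#' @param wage Dollars per hour.
#' @return Dollars per year.
#' @export
productivity_cost <- function(n_cases, p_work_loss, lost_hours, wage) {
  stopifnot(all(p_work_loss >= 0 & p_work_loss <= 1),
            all(lost_hours >= 0), all(wage >= 0))
  n_cases * p_work_loss * lost_hours * wage
}

#' Mortality cost via the value of a statistical life
#'
#' @param deaths Deaths per year. Vectorized.
#' @param vsl Value of a statistical life, dollars per death (applied
#'   uniformly, not age-adjusted).
#' @return Dollars per year.
#' @export
mortality_cost <- function(deaths, vsl) {
  stopifnot(all(deaths >= 0), all(vsl >= 0))
  deaths * vsl
}

#' Excess cost of long-term sequelae among hospitalized cases
#'
#' Sums, over pathogens and their declared sequelae (e.g. Guillain-Barre
#' syndrome after *Campylobacter*, hemolytic-uremic syndrome after
#' *E. coli* O157:H7, reactive arthritis), hospitalizations times the
#' sequela probability times its excess cost per case.
#'
#' @param hospitalizations A data frame with columns `pathogen` and
#'   `hospitalizations` (and optionally `draw`).
#' @param sequelae A data frame with columns `pathogen`, `probability`,
#'   `excess_cost` (and `draw` when per-draw); pathogens must be declared in
#'   `hospitalizations`.
#' @return Dollars per year (a vector per draw if `draw` is present, else a
#'   single total). Zero when no sequelae are declared.
#' @export
sequelae_cost <- function(hospitalizations, sequelae) {
  if (is.null(sequelae) || nrow(sequelae) == 0) return(0)
  if (!all(sequelae$pathogen %in% hospitalizations$pathogen)) {
    bad_param("sequelae.pathogen", "references an undeclared pathogen")
  }
  by <- intersect(c("pathogen", "draw"), names(sequelae))
  joined <- sequelae |>
    left_join(select(hospitalizations, all_of(c(by, "hospitalizations"))), by = by) |>
    mutate(cost = .data$hospitalizations * .data$probability * .data$excess_cost)
  if ("draw" %in% by) {
    joined |>
      group_by(.data$draw) |>
      summarise(cost = sum(.data$cost), .groups = "drop") |>
      pull(.data$cost)
  } else {
    sum(joined$cost)
  }
}

cost_components <- c("otc", "rx", "hcp", "ed", "hospital", "sequelae",
                     "productivity", "death_vsl")

# components that must be zero in each tier (the "--" cells of the cost table)
tier_zero_components <- list(
  mild = c("hcp", "ed", "hospital", "sequelae", "death_vsl"),
  moderate = c("hospital", "sequelae", "death_vsl"),
  severe = character()
)

#' Per-tier cost breakdown
#'
#' Assembles the eight cost components of one severity tier and their total:
#' `total = otc + rx + hcp + ed + hospital + sequelae + productivity +
#' death_vsl`. The tier composition rule is enforced: mild illness carries
#' only medication and productivity costs; moderate adds provider and
#' emergency-department visits; severe carries all eight.
#'
#' @param tier `"mild"`, `"moderate"` or `"severe"`.
#' @param otc,rx,hcp,ed,hospital,sequelae,productivity,death_vsl Component
#'   costs in dollars per year. Vectorized (e.g. one value per Monte Carlo
#'   draw).
#' @return A tibble with the tier, the eight components, and their `total`.
#' @examples
#' # moderate-tier published components sum to the published total
#' cost_breakdown("moderate", otc = 33.5e6, rx = 126.0e6, hcp = 615.0e6,
#'                ed = 924.9e6, productivity = 201.1e6)$total / 1e6
#' @export
cost_breakdown <- function(tier = c("mild", "moderate", "severe"),
                           otc = 0, rx = 0, hcp = 0, ed = 0, hospital = 0,
                           sequelae = 0, productivity = 0, death_vsl = 0) {
  tier <- match.arg(tier)
  comp <- list(otc = otc, rx = rx, hcp = hcp, ed = ed, hospital = hospital,
               sequelae = sequelae, productivity = productivity,
               death_vsl = death_vsl)
  for (z in tier_zero_components[[tier]]) {
    if (any(comp[[z]] != 0)) {
      bad_param(paste0(tier, ".", z),
                paste0("the ", tier, " tier cannot carry ", z, " costs"))
    }
  }
  out <- as_tibble(comp)
  out$total <- Reduce(`+`, comp)
  out$tier <- tier
  select(out, "tier", all_of(cost_components), "total")
}

#' Cost per case of illness
#'
#' @param total_cost Dollars per year. Vectorized.
#' @param n_cases Cases per year (strictly positive).
#' @return Dollars per case; zero cost gives zero.
#' @export
per_case_cost <- function(total_cost, n_cases) {
  if (any(n_cases <= 0)) abort("no cases", class = "aquaburden_no_cases")
  total_cost / n_cases
}
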