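# A minimal hand-computable scenario: every parameter a point mass, one
# activity, one illness, one pathogen. Expected values below are products
# by hand:
#   person-days = (0.2 * 1e6 + 0.5 * 2e5) * 10 = 3e6
#   AGI cases   = 3e6 * (0.04 - 0.01) = 9e4; moderate = 9e3, mild = 8.1e4
#   community   = 10 * 25.5 = 255; hosp = 255 * 0.1 * 2 = 51; deaths = 255 * 0.01 * 2 = 5.1
tiny_raw <- function() {
  pt <- function(v) list(family = "point", value = v)
  list(
    name = "tiny",
    population = list(reference_year = 2007, adult_population = 1e6,
                      child_population = 2e5),
    activities = list(list(name = "swimming",
                           participation_over16 = pt(0.2),
                           under16_share = pt(0.5),
                           mean_days_per_year = pt(10))),
    risks = list(list(activity = "swimming", illness = "agi",
                      p_exposed = pt(0.04), p_unexposed = pt(0.01))),
    severity = list(list(
      illness = "agi", moderate_fraction = pt(0.1),
      mild = list(p_otc = pt(0.5), p_rx = pt(0.1), p_work_loss = pt(0.4),
                  lost_hours = pt(2)),
      moderate = list(p_otc = pt(0.6), p_rx = pt(0.5), p_hcp = pt(0.8),
                      p_ed = pt(0.2), p_work_loss = pt(0.7),
                      lost_hours = pt(4)))),
    pathogens = list(list(name = "cryptosporidium", observed_cases = 10,
                          community_multiplier = 25.5, severe_correction = 2,
                          hosp_fraction = pt(0.1), death_fraction = pt(0.01),
                          hosp_cost = pt(8000),
                          sequelae = list(list(name = "hus",
                                               probability = pt(0.05),
                                               excess_cost = pt(1e5))))),
    costs = list(
      otc_per_user = pt(6), rx_per_user = pt(30), hcp_visit = pt(90),
      ed_visit = pt(700), wage_per_hour = pt(20), vsl = pt(7e6),
      severe = list(p_otc = pt(0.8), p_rx = pt(0.9), p_hcp = pt(0.9),
                    p_ed = pt(0.4), p_work_loss = pt(0.95),
                    lost_hours = pt(20), rx_per_user = pt(40),
                    hcp_visit = pt(200)),
      cpi_factors = list(
        list(year = 2007, series = "medical_commodities", factor = 1),
        list(year = 2007, series = "medical_services", factor = 1),
        list(year = 2007, series = "wages", factor = 1),
        list(year = 2001, series = "medical_services", factor = 1.18))),
    options = list(truncate_negative_ar = FALSE, n_iterations = 10, seed = 1)
  )
}

tiny_scenario <- function() as_scenario_config(tiny_raw())
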