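# aquaburden

Swimming, paddling, rowing, motor boating, and fishing on United States
surface waters carry an excess risk of gastrointestinal, respiratory, eye,
ear, and skin illness relative to staying dry. `aquaburden` estimates the
annual national case burden of that recreational waterborne illness and its
economic cost, with full uncertainty propagation. It is aimed at
environmental-health economists and water-quality analysts who need a
reproducible, scenario-driven cost-of-illness engine — for example to put
beach monitoring or wastewater-control budgets in context.

## The model in brief

* **Exposure.** Annual recreation events per activity are person-days:
  participation proportions × census population bases × mean days per
  recreator.
* **Sporadic illness.** Cohort-study exposed/unexposed illness
  probabilities give an attributable risk (risk difference)
  *AR = p<sub>e</sub> − p<sub>u</sub>* per recreation event; cases =
  events × AR, split into **mild** (no healthcare contact) and **moderate**
  (provider or emergency-department contact) tiers.
* **Severe illness.** Passive outbreak-surveillance counts are corrected
  for underreporting (community multiplier 25.5; 1.1 for vibriosis; 1.0 for
  *Naegleria fowleri*), multiplied by hospitalization/death fractions, and
  doubled for underdiagnosis of severe outcomes.
* **Costs.** Per severity tier *i*:

  Cost<sub>i</sub> = OTC<sub>i</sub> + Rx<sub>i</sub> + HCP<sub>i</sub> +
  ED<sub>i</sub> + Hospital<sub>i</sub> + Sequelae<sub>i</sub> +
  Productivity<sub>i</sub> + VSL<sub>i</sub>

  in 2007 USD, with consumer-price-index conversion for inputs quoted in
  other years and mortality valued at the value of a statistical life.
* **Uncertainty.** Every parameter is a sampleable distribution; a seeded
  Monte Carlo run (100,000 iterations by default) reports each output as a
  mean with the central 90% of values (C90: 5th–95th percentile).

The packaged `us2007_scenario()` encodes the 2007 United States parameter
book; unit costs and pathogen detail not published at full granularity are
calibrated reconstructions, documented in `vignettes/burden-methods.Rmd`
and generated by `data-raw/us2007.R`.

## Worked example

```r
library(aquaburden)
library(dplyr)

sc  <- us2007_scenario()
sim <- run_simulation(sc, n_iterations = 100000, seed = 42)
sim
#> <burden_sim> scenario 'us2007': 1e+05 iterations, seed 42
#>   total recreation events (mean): 4.043e+09 person-days/yr
#>   grand total cost: 2.89 billion (C90 2.07-3.76)

sim$tables$costs |> filter(component == "total")
#> # A tibble: 3 × 6
#>   tier     component        mean          p5         p95 n_draws
#>   <chr>    <chr>           <dbl>       <dbl>       <dbl>   <int>
#> 1 mild     total      756808448.  541953256.  984272472.  100000
#> 2 moderate total     1902290551. 1284059720. 2575732579.  100000
#> 3 severe   total      233627427.   81043937.  503502313.  100000

sim$tables$per_case
#> # A tibble: 3 × 5
#>   tier          mean       p5      p95 n_draws
#>   <chr>        <dbl>    <dbl>    <dbl>   <int>
#> 1 mild          9.43     8.22     10.7  100000
#> 2 moderate    227.     193.      262.   100000
#> 3 severe   294765.   97801.   652667.   100000
```

Reading this: about 4.04 billion recreation events produce roughly 89
million sporadic illnesses a year (9.4% of them moderate), around 780
hospitalizations and 31 deaths, and a total economic burden averaging
$2.89 billion in 2007 dollars, with a central-90% interval of about
$2.1–3.8 billion. Mild illness costs ~$9 per case; moderate illness
(provider/ED contact) ~$230; severe illness ~$295,000, dominated by
mortality valued at the VSL. `tidy(sim)` returns every summary cell as one
long tibble, `glance(sim)` a one-row overview, and `autoplot(sim)` C90
error-bar charts; `render_tables(sim, "report/")` writes CSV/JSON reports.

Other entry points: `read_scenario()`/`write_scenario()` for custom YAML or
JSON parameter books, `point_estimate()` for the deterministic point-mass
evaluation, `generate_scenario()` for synthetic scenarios with closed-form
truth tables, and a thin command-line wrapper in `inst/cli/aquaburden.R`
(`run`, `validate`, `synth`).

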