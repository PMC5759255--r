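---
title: "Estimating the national burden and cost of recreational waterborne illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the national burden and cost of recreational waterborne illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aquaburden)
library(dplyr)
```

## The model

Surface-water recreation (swimming and wading, paddling, rowing, motor
boating, warm-water fishing) carries an excess risk of acute
gastrointestinal illness (AGI) and of respiratory, eye, ear, and skin
symptoms relative to staying dry. `aquaburden` estimates the annual
national case burden and its cost with a three-branch model:

1. **Exposure.** For each activity, the number of recreators aged 16+ is
   the participation proportion times the non-institutionalized census
   population 16+; recreators under 16 are a share of the under-16 census
   population. Annual *recreation events* are person-days:
   $E_a = (R_a^{16+} + R_a^{<16}) \, d_a$, with $d_a$ the mean days per
   recreator per year. One event is one person-day of one activity.

2. **Sporadic illness.** Cohort studies of swimmers and incidental-contact
   recreators give, per activity group and illness type, the probability of
   illness if exposed ($p_e$) and if unexposed ($p_u$) over the same recall
   window. The attributable risk is the risk difference $AR = p_e - p_u$,
   applied per event: annual cases are $E_a \cdot AR_{a,i}$. Cases split
   into **mild** (no healthcare contact) and **moderate** (healthcare
   provider or emergency department contact) tiers by an illness-specific
   moderate fraction. Activity-illness pairs with no observed excess risk
   are *absent* from the configuration: they contribute zero cases and zero
   variance.

3. **Severe illness.** Hospitalizations and deaths come from passive
   outbreak surveillance, which undercounts. Observed pathogen-specific
   counts are scaled by a community multiplier (25.5 for most enteric
   pathogens, borrowed from foodborne-outbreak validation work; 1.1 for
   vibriosis, whose single cases are already captured; 1.0 for *Naegleria
   fowleri*, which is nearly always fatal and hence recognized), then
   multiplied by hospitalization and death fractions, then doubled
   (`severe_correction = 2`) because hospital and death records themselves
   underdiagnose.

Costs per severity tier $i$ follow one aggregation identity:

$$\mathrm{Cost}_i = OTC_i + Rx_i + HCP_i + ED_i + Hospital_i +
  Sequelae_i + Productivity_i + VSL_i$$

with the tier composition rule: mild illness carries only medication and
productivity terms; moderate adds provider and emergency-department
visits; severe carries all eight, including hospitalization, long-term
sequelae (Guillain-Barré syndrome after *Campylobacter*, hemolytic-uremic
syndrome after *E. coli* O157:H7, reactive arthritis), and mortality
costed at the value of a statistical life (VSL), applied uniformly because
the age distribution of severe outcomes is unknown. All costs are
expressed in reference-year (2007) dollars; parameters quoted in other
years carry a consumer-price-index tag (medical commodities, medical
services, or wages) and are converted on sampling.

## Uncertainty propagation

Every uncertain parameter is a `dist_spec` (point, uniform, normal,
truncated normal, triangular, PERT, lognormal, or empirical). A simulation
run draws all parameters independently `n_iterations` times from one
seeded stream in a fixed, documented order, evaluates the pipeline per
draw, and reports each output as its mean and **central 90% of values
(C90)** — the empirical 5th and 95th percentiles, computed by linear
interpolation between order statistics (the type-7 convention).

Numerical choices worth knowing:

* **Clamping, not rejection.** Draws outside a spec's bounds (for example
  proportions outside $[0, 1]$) are moved to the nearest bound. Rejection
  sampling would consume a data-dependent number of deviates and break
  seed-for-seed reproducibility; clamping keeps one vectorized deviate
  call per parameter. Analytic means (`dist_mean()`) use the clamped-normal
  and clamped-lognormal closed forms, so the deterministic oracle matches
  the sampler exactly.
* **Negative attributable risks propagate.** Several published exposed/
  unexposed confidence intervals admit negative risk differences; these are
  retained in the main analysis. `truncate_negative_ar` floors them at
  zero; by construction this can only increase mean case counts, and on
  the packaged scenario it moves the mean total cost by well under 5%.
* **Parameters quoted as mean + C90** are encoded as normal distributions
  with $\sigma = (p_{95} - p_{5}) / (2 \times 1.6449)$
  (`spec_from_c90()`); parameters quoted with 95% confidence intervals use
  $\sigma = (\mathrm{hi} - \mathrm{lo}) / (2 \times 1.96)$. Symmetric
  printed intervals are consistent with near-normal inputs; the original
  per-parameter families are not published.
* **Ratios are summarized per draw.** Per-case costs and the moderate
  share are computed within each draw and then averaged, so they are means
  of ratios, not ratios of means.

## The packaged 2007 United States scenario

`us2007_scenario()` encodes the 2007 reference year: census bases of
233.5 million adults (16+) and 63.3 million children, six activities with
published participation percentages, under-16 shares and days per
recreator, thirteen declared activity-illness risk pairs, five
moderate-severity fractions, and nine pathogens.

Two classes of inputs in that file are **calibrated reconstructions**, not
transcriptions, because the underlying detail is not published:

* unit costs and utilization probabilities (over-the-counter and
  prescription medication, provider and emergency visits, wages, lost
  hours, VSL, per-stay hospitalization cost), and
* pathogen-specific observed counts and hospitalization/death fractions.

Anchors that *are* published were fixed first (just over 50% of AGI cases
use over-the-counter medication, about 40% miss work, a 2007 wage of
\$19.60/h, a VSL near \$7.4M); the remaining free values were then solved
by a fixed-point loop (`data-raw/us2007.R`) so that the analytic mean of
every tier cost component reproduces its published national total, and so
that mean hospitalizations (~780) and deaths (~31) fall inside the
published 333–1696 and 16–67 ranges. Relative spreads (7% on utilization
probabilities, 10–15% on unit costs, lognormal shapes with $\sigma_{\log}$
0.25–0.6 for hospital costs, outcome fractions and the VSL) were chosen
once as field-typical magnitudes. Means are therefore reproduced by
construction; the simulated *intervals* are genuine model output.

```{r run, fig.width = 7, fig.height = 4}
sc <- us2007_scenario()
sim <- run_simulation(sc, n_iterations = 5000, seed = 42)
glance(sim)
sim$tables$costs |> filter(component == "total")
autoplot(sim, table = "cases")
```

(The default `options.n_iterations` is 100,000, matching the published
design; the smaller run above keeps the vignette quick. At 100,000
iterations the run takes under a minute and gives a grand total near
\$2.9 billion with a C90 of roughly \$2.1–3.8 billion.)

## Synthetic scenarios and what passing tests show

Because every reported cell is a sum of products of independently sampled
factors, its expectation is the same sum of products of factor means.
`generate_scenario()` draws random parameter books from realistic ranges
(participation 1–50%, implied attributable risks $-0.01$ to $0.05$,
multipliers in $\{1, 1.1, 25.5\}$), mixing all distribution families, and
carries that closed-form truth table; `mc_expectation_cells()` extracts
the matching Monte Carlo means and standard errors. The package's tests
require engine-vs-oracle agreement within four Monte Carlo standard
errors for every cell, exact collapse under point-mass scenarios, per-draw
cost conservation, and bit-identical output under a fixed seed.

The generator emulates the *structure* of the national analysis — aggregate
parameter books, independent draws — not individual-level cohort data. A
passing suite therefore validates the arithmetic and the uncertainty
propagation, not the epidemiology: correlated parameters, multi-illness
episodes, age structure, and seasonality are all outside the model, as
they are outside the published analysis.

## Known limitations

* Independence everywhere: the published analysis describes no correlation
  structure, so none is modelled; if participation and days per recreator
  covary, interval widths are misstated.
* The moderate fraction is illness-specific but activity-invariant (only
  the pooled value per illness is published).
* Severe cases are additional to, not subtracted from, the sporadic
  mild/moderate counts, mirroring the two separate estimation paths.
* Concurrent illnesses are costed separately (a person with AGI and
  respiratory symptoms who sees a provider once is charged twice), which
  can overstate costs.
* The "25.5 other cases per detected case" phrasing admits a ×26.5
  reading; the multiplier is applied as ×25.5, and the alternative is one
  config edit away.
* Harmful-algal-bloom illness, age-stratified burden, and payer
  decomposition are out of scope.
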