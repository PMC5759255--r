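Package: aquaburden
Title: National Burden and Cost of Recreational Waterborne Illness
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A seeded Monte Carlo cost-of-illness pipeline for surface-water
    recreation. Scales activity participation proportions and days-per-recreator
    into annual recreation events (person-days), converts cohort-study
    attributable risks into annual sporadic illness cases split into mild and
    moderate severity tiers, estimates hospitalizations and deaths from passive
    outbreak-surveillance counts via underreporting multipliers, and aggregates
    direct and indirect costs (medications, provider and emergency visits,
    hospitalization, sequelae, lost productivity, and value-of-statistical-life
    mortality costs) with consumer-price-index adjustment. Every uncertain
    parameter is a sampleable distribution; outputs are reported as means with
    central-90% intervals. Ships a packaged 2007 United States scenario and a
    synthetic-scenario generator with closed-form expected outputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
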