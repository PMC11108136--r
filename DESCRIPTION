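Package: hlemms
Title: Health Expectancies from Multistate Microsimulation of Morbidity
    and Mortality Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates life expectancy and state-specific healthy life
    expectancy for a population from individual two-year morbidity and
    mortality records. Annual transition probabilities between six
    morbidity states plus death are estimated by sex and age group,
    expanded to single years of age with natural cubic splines, and fed
    to a Monte Carlo microsimulation of lifetime health trajectories
    from which expectancies are computed with the standard demographic
    person-years formula. Includes an analytic absorbing-chain
    calculator used as a deterministic cross-check, a classical
    Sullivan-method (prevalence times life-table person-years)
    comparator, a period life-table builder, and a synthetic-population
    generator with known ground-truth dynamics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
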