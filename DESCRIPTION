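Package: tephrisim
Title: Physiologically Based Demographic Models of Tropical Tephritid Fruit Flies
Version: 0.1.0
Authors@R:
    person("CASAS", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weather-driven, age-structured simulation of the population
    dynamics of four tropical tephritid fruit flies (Mediterranean fruit fly,
    melon fly, oriental fruit fly, Mexican fruit fly). Life stages are modelled
    with time-invariant distributed-maturation-time (Erlang) delay chains driven
    by daily temperature; reproduction is computed with a ratio-dependent,
    demand-driven functional response modulated by temperature and relative
    humidity scalars. Includes a seeded synthetic daily weather generator,
    multi-year lattice runs aggregated into a normalized favorability index
    with ESRI ASCII grid export, and an ordinary-least-squares marginal-effects
    regression for post-hoc analysis of simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
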