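Package: agforesight
Title: Desk-Scale Foresight Modelling of Agricultural Investment and Hunger
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A stylized multi-market partial-equilibrium model of world
    agriculture coupled to a reduced-form economy-wide income feedback, a
    perpetual-inventory R&D investment module with inverse costing of
    productivity targets, climate yield-shock scenarios, and hunger-prevalence
    indicators derived from per-capita calorie availability.  Generates
    seeded synthetic world configurations calibrated to published 2010
    anchors, runs no-climate-change, climate-change, and comprehensive
    investment scenarios to 2030, and reports incomes, commodity price
    indices, kilocalorie availability and the population at risk of hunger
    by region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
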