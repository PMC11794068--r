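Package: sdpricing
Title: System-Dynamics Simulation of Value-Based New-Drug Pricing Premiums
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small discrete-time system-dynamics engine (forward Euler stocks,
    first-order information delays, dependency-ordered algebra) together with a
    declarative model of Japan's premium system for new-drug pricing decisions.
    Bundles the pricing-decision evaluation model (value, marketability I/II,
    pediatrics and SAKIGAKE premium subsystems feeding one accumulating stock),
    closed-form steady-state analysis, an integration-step stability test,
    one-at-a-time sensitivity analysis with impact ranking, a JSON model-file
    dialect, tidy CSV exporters, a seeded random-model generator for property
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
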