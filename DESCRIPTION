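Package: tariffmed
Title: Integrated Macroeconomic, Nutrition and Cardiovascular Health
    Simulation of Food Import Tariff Policy
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A recursively-dynamic multi-sector computable general
    equilibrium (CGE) economy coupled to household-specific Almost Ideal
    Demand Systems, a fatty-acid/cholesterol nutrition transmission
    module, stratified clinical cardiovascular outcome lookups, a
    cohort-component demographic projection with mortality feedback,
    labour-supply and health-cost feedbacks into the economy, and a
    land-use-change greenhouse-gas satellite module.  Includes a
    deterministic synthetic-economy fixture generator calibrated to
    published sectoral trade and tariff share targets, scenario
    orchestration for tariff elimination and uniform 30% tariff
    experiments, efficiency and health-pathway decompositions, and
    cost-effectiveness reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    numDeriv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
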