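Package: mtctrends
Title: Mean Temperature of the Catch and Community Tropicalization Indicators
Version: 0.1.0
Authors@R:
    person("Pelagic", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify climate-driven tropicalization of pelagic
    fishery catches. Computes the Mean Temperature of the Catch (MTC) from
    year-by-species biomass matrices and species thermal preferences,
    classifies species into warm- and cold-water affinity groups, fits and
    compares linear and penalized cubic-spline trend models, runs
    leave-one-species-out sensitivity analyses and time-lagged
    environmental driver models, and analyses catch composition through
    Hellinger transformation, multivariate regression trees, principal
    coordinates analysis, total beta-diversity decomposition (species and
    year contributions with permutation inference), and temporal
    beta-diversity indices partitioned into biomass gains and losses. A
    synthetic-data generator with planted trends supports testing every
    stage without external fishery databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
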