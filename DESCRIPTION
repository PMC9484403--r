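Package: hindcastSDM
Title: Hindcast-Validated Species Distribution Models for Coastal Ecotones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds presence-background maximum-entropy species distribution
    models from monthly climate normals, validates them by hindcasting into
    past periods of documented community dominance, and projects habitat
    suitability into future climate windows. Includes computation of the 19
    bioclimatic variables from monthly minimum temperature, maximum
    temperature and precipitation grids, correlation-based predictor pruning,
    MaxEnt-style feature construction with L1-regularized fitting and cloglog
    output, spatial checkerboard partitioning, AICc model selection, partial
    ROC evaluation, jackknife variable importance, and region-level
    suitability aggregation (sums, group averages, dominance ratios, percent
    changes). A synthetic climate and occurrence generator makes the full
    pipeline testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
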