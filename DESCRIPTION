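Package: thermoscope
Title: Aerobic Scope Thermal Performance and Habitat Thermal Regimes for
    Aquatic Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes intermittent-flow respirometry oxygen traces into
    per-animal resting and maximum metabolic rates, derives absolute and
    factorial aerobic scope, fits thermal performance curves by nonlinear
    least squares with AIC-based model selection, locates thermal optima
    and optimum breadth (Topt, Topt90, Topt80) on dense prediction grids,
    and summarizes habitat temperature-logger series into stream thermal
    regime metrics (7-day average daily maxima, degree days and degree
    hours, diel range, threshold exposure, winter freezing statistics)
    and thermal safety margins. Includes a synthetic-data generator for
    respirometry traces, trial cohorts and habitat logger series with
    known ground truth, and bundled fitted metabolic models for two
    Madison River salmonfly (Pteronarcys californica) nymph populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
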