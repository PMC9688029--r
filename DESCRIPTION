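Package: lenstock
Title: Length-Based Stock Assessment for Data-Limited Demersal Fisheries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Length-based stock assessment toolkit for data-limited demersal
    fisheries, built around the silver scabbardfish (Lepidopus caudatus)
    fishery of the Azores as a worked case. Estimates von Bertalanffy growth
    parameters from monthly length-frequency data by ELEFAN restructuring and
    a genetic-algorithm search with bootstrap confidence intervals; derives
    total mortality from the linearized length-converted catch curve, natural
    mortality from a battery of fourteen empirical estimators, and fishing
    mortality and exploitation rate from these; fits two-part (hurdle)
    additive models for zero-inflated survey catch rates with spatial and
    depth smooths and a substrate factor; standardizes fishery-dependent
    catch rates with hurdle-lognormal GLMs and least-squares means; and
    compares min-max-normalized abundance-index trends by ANCOVA with Tukey
    contrasts. A seeded synthetic-data generator emulates the survey,
    landings and trip records the analyses consume, so the whole pipeline is
    testable without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    emmeans,
    car,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
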