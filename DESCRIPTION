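Package: reedcarbon
Title: Growth Dynamics and Carbon Sequestration of Common Reed Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the seasonal biomass dynamics of Phragmites australis
    (common reed) with a phenology-driven, five-compartment growth model using
    a 1 cm layered canopy and daily fourth-order Runge-Kutta integration, and
    converts the simulated net primary production into daily, monthly and
    annual carbon sequestration. Also provides empirical retrieval of
    above-ground biomass from multi-band surface-reflectance imagery,
    class-separability and classification-accuracy metrics, one-at-a-time
    sensitivity analysis, deterministic grid calibration against sparse
    biomass observations, nutrient-availability scenario experiments, and
    synthetic generators for meteorological forcing, reflectance scenes and
    biomass observations so the whole pipeline is testable without field or
    satellite imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
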