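Package: soiltemp
Title: Empirical Soil-Temperature Modelling for Snow-Covered Boreal Forest Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-timestep empirical soil-temperature simulation for
    seasonally frozen, snow-covered forest soils, with exponential snow
    insulation damping, an apparent (latent-heat) soil heat capacity and a
    lower-boundary heat-flow extension. Includes distribution-mapping
    (quantile-mapping) bias correction of regional climate model series,
    Monte Carlo calibration with Nash-Sutcliffe scoring and behavioral-run
    selection, degree-day snowpack modelling, synthetic weather generation
    for testing, climate-ensemble projection summaries and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fitdistrplus,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
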