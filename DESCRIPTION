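Package: dwrisk
Title: Probabilistic Health Risk Assessment of Drinking-Water Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening groundwater quality against WHO drinking-water
    guidelines and for probabilistic (Monte Carlo) assessment of human exposure
    to waterborne contaminants. Lognormal concentration and body-weight models
    and uniform intake models are combined into chronic daily intake
    simulations; hazard quotients against USEPA oral reference doses and
    threshold exceedance probabilities are reported for several population
    groups (adult male, adult female, children aged 1-3). Ships the summary
    statistics, guideline values and reference doses of a 115-well Gaza Strip
    groundwater survey as packaged fixtures, together with a synthetic
    well-measurement generator emulating that survey, including left-censored
    trace metals and single-well point-source detections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    fitdistrplus,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
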