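Package: dielcarbon
Title: Stream Metabolism and Carbon Dioxide Evasion from Diel Sensor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates gross primary production, ecosystem respiration and
    gas exchange in running waters from continuous dissolved oxygen records,
    and links these metabolic rates to carbon dioxide evasion at the reach
    scale. Provides closed-form gas physics (Schmidt-number scaling, oxygen
    saturation, Henry's law solubility, barometric correction), night-time
    regression estimation of the gas exchange coefficient and its relation
    to discharge, a Bayesian diel oxygen model fitted by random-walk
    Metropolis sampling with discharge-informed priors, day-level quality
    control, carbon dioxide evasion and diel flux metrics, segment-wise
    carbon dioxide mass balance for losing and gaining reaches, and a seeded
    synthetic sensor-deployment generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
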