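Package: rhizosense
Title: Electrochemical Phenotyping of Plant Root Ion Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for real-time electrochemical monitoring of the
    plant root environment. Converts raw sensor time series (impedance
    magnitude, pH electrode potential, hydrogen peroxide current) into
    concentrations via per-salt log-log and linear calibrations, estimates
    collective root ion-uptake rates by fitting a power-law decay c = B * t^k
    to the post-addition concentration transient, normalizes uptake against
    plant-free controls, compares uptake across nutrient and heavy-metal salt
    categories (one-way ANOVA, Tukey-Kramer post hoc with compact letter
    display), and predicts binned uptake classes from ion physicochemical
    descriptors with gradient-boosted trees under cross-validation. Includes a
    seeded synthetic trace generator so the whole chain is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
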