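Package: ribofis
Title: Mamdani Fuzzy Inference Modelling of Riboflavin Production from
    One-Factor-at-a-Time Fermentation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting microbial riboflavin (vitamin B2) yield from
    fermentation medium composition with a Mamdani fuzzy inference system.
    Provides a generic engine (triangular membership functions, min/max
    inference, centroid defuzzification), the concrete linguistic variables for
    four semi-defined-medium components (casamino acid, GTP, sodium acetate,
    glycine) and the riboflavin output, Wang-Mendel rule induction from
    one-factor-at-a-time (OFAT) dose-response tables, validation metrics
    (percent variation, RMSE, Pearson correlation), a synthetic OFAT
    dose-response generator for end-to-end testing, and a small pipeline layer
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
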