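Package: ursaconflict
Title: Harvest-Based Population Reconstruction and Human-Bear Conflict Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking a hunted black bear population to yearly
    human-bear complaint counts. Implements cohort-based (Downing-style)
    population reconstruction from age-at-harvest records with sex-misreport
    correction, plus-group pooling and a non-hunting-mortality scale-up; a
    natural-food abundance index built from categorical fruit surveys;
    regression imputation of complaint totals in years when only on-site
    visits were recorded; and an AICc-based competition of linear complaint
    models with Akaike weights, adjusted R-squared, variance inflation
    factors and residual autocorrelation diagnostics. An individual-based
    simulator of a harvested age-structured population provides synthetic
    data with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    car,
    jsonlite
Config/testthat/edition: 3
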