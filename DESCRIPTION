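Package: nutripair
Title: Validation of Paired Food-Database Dietary Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating consumer-app dietary records against a
    reference food-composition database. Learns per-nutrient upper limits
    per food portion on a training phase by cross-database correlation
    maximization, cleans a held-out phase, quantifies method agreement
    (correlation with a Shapiro-Wilk normality gate, paired location
    tests, Bland-Altman bias analysis), and simulates the statistical
    power lost -- and the sample-size inflation needed to compensate --
    when an error-prone nutrient measure replaces the reference in
    correlation-based study designs. Includes a seeded synthetic-cohort
    generator with auditable contamination for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
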