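Package: scsolub
Title: Solubility of Drugs in Supercritical Carbon Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement-scale modelling of solid-drug solubility in
    supercritical carbon dioxide. Implements the five classical
    density-based semi-empirical correlations (Chrastil, modified
    Chrastil, Mendez-Santiago-Teja, Bartle, Kumar-Johnston) behind a
    single fitting interface with standard S3 methods, dissolution
    enthalpy extraction, crossover-pressure and self-consistency
    analyses, a solid-fluid equilibrium route through the
    Esmaeilzadeh-Roshanfekr cubic equation of state with two-parameter
    van der Waals mixing rules, staged genetic-algorithm and
    differential-evolution parameter estimation, a reference-quality
    Span-Wagner carbon dioxide density surface, Joback and
    Constantinou-Gani group-contribution property estimation, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
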