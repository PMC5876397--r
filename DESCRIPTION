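Package: transwellr
Title: Translocation Kinetics and Permeability Analysis for Transwell Barrier Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of in vitro barrier translocation experiments performed in
    two-chamber (Transwell) insert systems, with an emphasis on placental
    trophoblast/endothelial mono- and co-culture barriers. Provides
    sampling-corrected cumulative transported mass for sample-and-replace
    schedules, percent-of-initial-dose time courses, permeability coefficients
    and membrane-corrected apparent permeability via the series-resistance
    relation, TEER blank subtraction and area normalisation, nanoparticle
    mass-to-number dosimetry, exact two-sided Mann-Whitney comparisons for
    small replicate groups, and an event-driven two-compartment transport
    simulator that generates complete synthetic studies with known ground
    truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
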