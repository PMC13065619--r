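Package: qfasadiet
Title: Diet Reconstruction from Fatty Acid Signatures by Exhaustive
    Simplex Search (QFASA)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative fatty acid signature analysis (QFASA) for
    terrestrial herbivores: estimates the proportional contribution of
    candidate food sources (e.g. grass, roots, yak feces) to a consumer's
    diet by exhaustively searching the diet-proportion simplex for the
    mixture of food fatty-acid signatures that minimizes the summed
    absolute deviation from the consumer's stored-fat signature.
    Includes derivation of per-fatty-acid calibration coefficients from
    index animals, a negative-control comparison against consumers known
    not to eat the candidate foods, cohort-level reporting, and a seeded
    synthetic-data generator for food libraries and consumer cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
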