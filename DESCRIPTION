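Package: twinace
Title: Classical Twin-Design ACE Modelling for Continuous and Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variance decomposition for the classical twin design: Falconer
    estimates and maximum-likelihood ACE models for continuous phenotypes,
    liability-threshold ACE models and tetrachoric correlations for binary
    choice traits, and five-group sex-limitation models with qualitative and
    quantitative nested tests. Includes a synthetic twin-cohort generator
    with known ACE structure (continuous phenotypes, threshold-determined
    binary choices, and selection of achievement into choosers), phenotype
    corrections (age/sex residualization, rank-based inverse-normal
    transform), descriptive tables, profile-likelihood confidence
    intervals, boundary-corrected likelihood-ratio tests, and
    simulation-based power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
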