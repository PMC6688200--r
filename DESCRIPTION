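Package: enrf
Title: Elderly Nutrient-Rich Food Scores and the NU-AGE Diet Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Elderly Nutrient-Rich Food (E-NRF) family of
    nutrient-density scores for foods and diets of older adults, including
    the E-NRF7.3 variant (seven nutrients to encourage, three to limit, per
    100 kcal with capping at 100% of the dietary reference value), and the
    16-component NU-AGE index of adherence to European food-based dietary
    guidelines for the ageing population. Provides energy-weighted
    individual diet scores, food-group summaries and contribution
    decompositions, an evaluation protocol (Spearman correlation and age-
    and sex-adjusted regression with sensitivity splits), a seeded
    synthetic food-composition and cohort generator for validation without
    survey data, and CSV readers and writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
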