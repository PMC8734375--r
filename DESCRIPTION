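Package: rxmass
Title: Prescribed Active-Ingredient Mass from Practice-Level Prescribing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the prescribed mass (in kg) of each active
    pharmaceutical ingredient (API) from monthly practice-level
    prescribing extracts. BNF presentation codes are resolved through a
    SNOMED mapping and a dm+d-style product hierarchy (AMP, VMP, VMPP,
    AMPP, ingredient strengths) to ingredient, strength and medicinal
    form; per-record masses are then aggregated by practice, postcode,
    month, region and form. Includes practice geocoding from postcode
    lookups, point-in-polygon region assignment, targeted and
    non-targeted reporting tables with plots, and a deterministic
    synthetic-fixture generator with a ground-truth ledger so the whole
    pipeline can be verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    purrr,
    stringr,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
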