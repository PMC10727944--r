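Package: muroseek
Title: Muropeptide Identification and Quantification from Deconvoluted LC-MS Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural analysis of bacterial peptidoglycan from deconvoluted
    LC-MS feature lists. Parses muropeptides written in gm-notation, computes
    neutral monoisotopic masses, dynamically generates theoretical databases of
    cross-linked dimers and trimers (4-3, 3-3 and the non-canonical 1-3
    chemistry), matches observed features within a ppm tolerance with
    retention-time-windowed cleanup of adduct and in-source satellite signals,
    and summarises peptidoglycan composition (cross-linking index, glycan chain
    length, 1-3 cross-link content). Includes a synthetic feature-list
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
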