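Package: nscglioma
Title: Multistage Neural-Stem-Cell Model of Glioma Incidence Across the Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models age-specific glioma incidence as the accumulation of
    oncogenic mutations over cell divisions in an exponentially declining,
    increasingly proliferative neural stem cell (NSC) pool. Extends the
    classical Armitage-Doll multistage framework with an empirically
    anchored division-rate schedule, a Poisson approximation of per-cell
    mutation counts (with an exact binomial cross-check), and a sequence
    multiplicity factor for the temporal ordering of oncogenic hits.
    Provides calibration of the NSC decay constant and sequence
    multiplicity against age-grouped incidence tables, a sweep over the
    minimum number of oncogenic mutations, parametric bootstrap confidence
    bands, scenario comparison of constant versus increasing division
    rates, a synthetic demographic-table generator, and a packaged glioma
    proto-oncogene set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
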