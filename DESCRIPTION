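Package: breedclim
Title: Climate Sensitivity of Wheat Breeding Nursery Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the climate sensitivity of wheat yields from
    multi-site breeding nursery trials. Converts daily station weather into
    thermal exposure indices (freezing, growing, and extreme growing
    degree-days) using a cosine hourly temperature model, collapses trial
    entries into percentile genotype series alongside a constant check
    variety, fits fixed-effects panel regressions of log yield on climate
    with site-specific quadratic time trends, estimates warming
    counterfactual yield impacts with bootstrap confidence intervals, and
    projects yields under climate scenarios. Includes a synthetic-data
    generator with recoverable ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
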