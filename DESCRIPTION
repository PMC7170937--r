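Package: firesink
Title: Fire-Constrained Terrestrial Carbon Cycle Modelling and Model-Data Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A six-pool terrestrial carbon box model with a prescribed
    burned-area fire module, Bayesian model-data fusion by Metropolis-Hastings
    MCMC against multi-stream land-surface observations, counterfactual
    burned-area experiments that separate the direct (combustion) and indirect
    (post-fire carbon-cycle) effects of fire decline, burned-area statistics,
    and airborne-fraction carbon-budget accounting. Includes a synthetic-data
    generator so the full pipeline runs end-to-end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
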