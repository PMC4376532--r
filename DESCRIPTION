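Package: nutlat
Title: Evolution of Nutritional Latitude Under Contest Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Agent-based simulation of foraging in a two-nutrient geometric
    nutrient space, coupling the Geometric Framework of nutrition with
    contest competition over limited feeding slots and an evolutionary
    algorithm acting on a heritable tolerance of nutritional imbalance
    ("nutritional latitude"). Individuals navigate from a common origin
    towards an intake target along food rails, fight fitness-dependent
    dominance contests when food is scarce, and may spontaneously abandon
    imbalanced foods. The package provides single-generation behavioural
    experiments, multi-generation evolutionary runs under
    fitness-proportionate or truncated selection, frequency-dependence
    grids, competition sweeps with replicate orchestration, tidy
    summaries, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
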