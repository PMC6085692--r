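Package: cladediv
Title: Clade-Level Genetic Divergence and Its Phylogenetic Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of why species differ in average
    genetic divergence among their populations. Computes patristic distances
    from within-species phylogenies, average between-locality divergence per
    clade, great-circle geographic distances, environmental heterogeneity from
    a principal-components summary of bioclimatic variables, and species ages
    from an ultrametric chronogram; fits phylogenetic generalized least
    squares (PGLS) regressions under a Brownian-motion covariance with
    likelihood-ratio backward model selection. Includes a synthetic-data
    generator with known effect sizes so the full pipeline can be exercised
    and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
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
    optparse,
    nlme,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
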