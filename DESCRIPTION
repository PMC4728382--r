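Package: rveps
Title: Rare-Variant Association Tests with Extreme Phenotype Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based region tests for the association of rare
    genetic variants with quantitative traits. Implements burden score
    tests and joint common-effect/variance-component score tests under
    two study designs, random sampling of a continuous trait and
    extreme-phenotype sampling in which the upper and lower trait tails
    are dichotomized into cases and controls, with Fisher and minimum-p
    combination of the component p-values calibrated by a shared
    permutation pool. Includes a haplotype-pool simulator for
    rare-variant-dominated regions and experiment drivers estimating
    empirical type I error and power over the designs' parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
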