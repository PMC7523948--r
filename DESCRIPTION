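Package: foodwebkit
Title: Food-Web Metrics and Permutational Multivariate Statistics for
    Disturbance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing invertebrate prey availability and fish diet
    composition around a large ecological disturbance. Converts invertebrate
    body measurements to dry mass and energy with taxonomic fallback, computes
    numeric and energetic density, taxa richness and terrestrial fractions,
    an energy-based Index of Relative Importance for prey selectivity,
    Bray-Curtis resemblance with dummy-species handling, and a from-scratch
    permutational test suite (PERMANOVA with Type III sums of squares and
    residual permutation under a reduced model, pairwise pseudo-t tests with
    Bonferroni correction and Monte Carlo fallback, ANOSIM, SIMPER, and
    non-metric multidimensional scaling). Includes a synthetic community and
    diet simulator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
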