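Package: spongeflux
Title: Isotope-Tracer Flux Analysis for Sponge Holobiont Feeding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carbon-13 and nitrogen-15 tracer feeding experiments on
    sponge holobionts. Converts bulk tissue and dissolved inorganic carbon
    isotope measurements into biomass-normalised assimilation and respiration
    rates and assimilation-to-respiration efficiencies, quantifies
    compound-specific tracer incorporation into phospholipid-derived fatty
    acids (PLFA) with biomarker classification and de novo synthesis
    detection, and provides the permutational statistics used to compare
    species and food sources (PERMANOVA with type III sums of squares,
    permutation and Monte Carlo p-values, pairwise tests, Welch's t).
    Includes a forward simulator of complete feeding experiments with known
    ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
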