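Package: qcindex
Title: Quality of Care Index Construction from Burden-of-Disease Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a 0-100 quality-of-care index (QCI) for a cause of
    disease from Global Burden of Disease style panels. Four secondary
    burden ratios (mortality-to-incidence, DALY-to-prevalence,
    prevalence-to-incidence, YLL-to-YLD) are computed per stratum and
    summarized by the first principal component, oriented so that higher
    scores mean better care and rescaled to 0-100. Companion analyses
    include gender-disparity ratios of the index and a three-factor
    counterfactual decomposition of incidence-count change into population
    growth, population aging, and age-specific rates. A synthetic panel
    generator with a known latent care-quality scalar per location makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
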