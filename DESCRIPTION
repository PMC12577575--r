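Package: paternitypower
Title: Power Analysis for Multiple-Paternity Sampling Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo power analysis for parentage sampling designs in
    populations with multiple paternity. Simulates egg fertilization within
    single clutches under six paternal-contribution modes to estimate the
    probability of identifying all sires as a function of offspring sample
    size, converts the resulting identification probabilities into Bayesian
    posteriors on the true number of sires given the number detected, and
    simulates entire breeding and nesting seasons (polyandrous and
    polygynous mating, clutch laying, partial clutch sampling) to estimate
    the confidence of identifying every breeding male. Default demographic
    parameters describe a green sea turtle nesting population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
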