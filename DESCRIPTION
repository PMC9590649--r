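Package: cellallometry
Title: Diminishing-Returns Models of Cell Type Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the number of cell types scales with the
    total number of cells across organisms. Implements an evolutionary
    cost/benefit model in which each cell-type segregation event carries a
    power-law fitness cost and a power-law fitness benefit that shrinks
    geometrically with the number of existing cell types, together with its
    closed-form capacity K = A + B*log10(N) and a discrete forward simulator.
    Fits four Bayesian regression models of log10 cell-type number against
    log10 cell number (double power law or diminishing-returns mean, constant
    or linearly varying standard deviation) by Markov chain Monte Carlo,
    summarizes posteriors with highest density intervals, regression-curve and
    posterior-predictive bands, and compares models by leave-one-out expected
    log predictive density with Pareto-smoothed importance sampling. Includes
    a synthetic-data generator emulating the published cell-type survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
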