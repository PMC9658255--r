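Package: aiyugel
Title: Reaction-Kinetics Modelling of Enzyme-Catalyzed Calcium-Pectin Gelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward modelling and analysis of enzyme-catalyzed ionic gelation
    of high-methoxyl pectin (the aiyu gel system). Solves the calcium-binding
    reaction-kinetics ODE with pseudo-first-order enzymatic demethylation,
    converts the binding ratio into concentrations of point-like crosslinks,
    short junction zones and egg-box junction zones via geometric run-length
    statistics, and maps crosslink densities to storage and loss moduli with a
    percolation-thresholded network model combining Winter critical-gel,
    fractional Maxwell and fractional Kelvin-Voigt elements. Includes gel-point
    and inflection-point detection for rheometer time sweeps, closed-form
    limiting solutions for the calcium-controlled, enzyme-limited and
    enzyme-controlled kinetic regimes, empirical stoichiometry relations for
    the critical binding ratios, a synthetic time-sweep generator with a
    multiplicative noise model, and least-squares parameter estimation with
    multistart local optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
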