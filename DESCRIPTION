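Package: sgewash
Title: Two-Step Steady-State Model of Second-Gas Elimination During
    Nitrous Oxide Washout
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state model of heterogeneous pulmonary gas exchange
    during nitrous oxide elimination. Net transfer of a trace ("second")
    inert gas is decomposed into a constant-volume component (Step 1) and
    the extra elimination carried by the gas-phase volume expansion that
    accompanies nitrous oxide washout (Step 2), across a multicompartment
    lung with a log-normal distribution of ventilation-perfusion ratios
    parameterized by a mismatch index sigma. Provides closed-form
    single-unit solutions, lung construction, calibration of mixed-venous
    nitrous oxide to a target whole-lung elimination rate, sweeps over
    sigma and over blood/gas solubility, distribution profiles, figure
    rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
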