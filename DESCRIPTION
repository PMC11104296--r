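Package: ambiprospect
Title: Prospect Theory with Ambiguous Outcome Magnitudes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of an eight-condition monetary gambling
    task in which some payoffs are displayed as ambiguous ("$?"/"-$?").
    Implements an ambiguity-augmented prospect theory choice model (utility
    curvature, loss aversion, and multiplicative ambiguity weights on the
    rational mean value of hidden payoffs), per-subject maximum-likelihood
    fitting of seven model variants with multi-start optimisation, model
    comparison by AIC, pseudo-R2 and cross-validated choice accuracy,
    parameter and gambling-rate recovery diagnostics, and group-level
    inference including Holm-Bonferroni corrected tests and trait-association
    regressions on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests: testthat (>= 3.0.0), jsonlite, withr, ggplot2, readr
Config/testthat/edition: 3
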