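Package: npyield
Title: Equilibrium Yield Prediction and Optimization for Nucleoside
    Phosphorylase Transglycosylations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modelling of nucleoside phosphorylase-catalyzed
    transglycosylation reactions, in which a sugar donor nucleoside
    glycosylates a free nucleobase via a pentose-1-phosphate intermediate.
    Provides the closed-form ideal (zero-phosphate) yield from the net
    equilibrium constant K_N = K1/K2, a full coupled-equilibrium solver
    with complete mass balance over all six species, reaction-design
    inversions (sugar donor excess for a target yield, phosphate budget
    for a tolerated yield loss, K1 x K2 yield landscapes), estimation of
    apparent equilibrium constants of phosphorolysis from endpoint
    composition measurements with bootstrap confidence intervals, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
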