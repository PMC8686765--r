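Package: fermkin
Title: Kinetic and Stoichiometric Analysis of Fermentative Metabolism Under
    Enforced ATP Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the physiology of Escherichia coli under
    enforced ATP wasting. Implements a kinetic model of anaerobic central
    fermentative metabolism (convenience kinetics with allosteric
    regulation, including the dual ADP/ATP dependency of
    phosphofructokinase), steady-state response scans over ATPase
    expression, Monte Carlo metabolic control analysis with
    steady-state-preserving parameter sampling, stoichiometric metabolic
    flux analysis that estimates ATPase fluxes from measured exchange
    rates by ATP-maintenance maximization, and the experimental rate and
    yield arithmetic for fermentation time courses, together with a
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
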