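Package: hipbasim
Title: Deterministic and Stochastic Models of the HipBA Toxin-Antitoxin
    Persistence Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action models of the Escherichia coli hipBA
    toxin-antitoxin operon for studying bacterial persistence. Provides the
    wild-type regulatory network and two alternative architectures
    (transcriptionally uncoupled genes and feedback-free expression), a
    stiff deterministic backend with equilibrium finding, a quasi-steady-state
    reduction with phase-plane nullcline analysis, Monte-Carlo multistability
    scans over log-normally sampled rate constants, an exact Gillespie
    stochastic simulator, and statistics of the persistence ratio
    R = free HipA / (free HipA + free HipB), including persistence-event
    detection and architecture comparisons by mean and Fano factor of R.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
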