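Package: bnflux
Title: Gaussian Bayesian Network Constraints for Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates probabilistic gene-regulatory networks into
    constraint-based models of metabolism. A Gaussian Bayesian network is
    parameterized from gene-expression data by local regressions; exact
    evidence propagation predicts transcript abundances under in-silico
    perturbation of a transcription factor; predicted enzyme fold-changes
    are aggregated onto reactions (including a kinase-mediated 1/alpha
    inhibition rule) and embedded as soft flux targets in a least-squares
    problem under steady-state equality and irreversibility inequality
    constraints. The feasible flux polytope is explored by uniform
    mirror-reflection Markov chain Monte Carlo sampling with Geweke and
    Gelman-Rubin convergence diagnostics, and evidence sweeps report
    objective (e.g. net ATP production) response curves and per-reaction
    flux fold-changes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    MASS,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
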