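Package: lgbn
Title: Linear-Gaussian Bayesian Networks for Tiered Randomised-Trial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Score-based structure learning for linear-Gaussian Bayesian
    networks under temporal tier constraints, with Structural
    Expectation-Maximization for incomplete data, bootstrap arc-strength
    model averaging to a consensus directed acyclic graph, nested
    cross-validated predictive validation, logic-sampling conditional
    queries, and arc-zeroing intervention simulations that decompose total
    effects into pathway contributions. Includes a synthetic generator for
    randomised-trial change-score data (a binary treatment group plus early
    and late change scores of ten outcomes) so the whole pipeline can be
    exercised and benchmarked without access to trial records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
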