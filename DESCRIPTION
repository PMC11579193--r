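Package: pksearch
Title: Machine-Learning and Local Downhill Search over Discrete
    Pharmacometric Model Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid global/local optimization of nonlinear mixed-effect
    (population pharmacokinetic) model structure. A discrete search space is
    defined by a tokens document of mutually exclusive text-fragment options
    per dimension; candidate model definitions are rendered from a template;
    a penalized fitness (objective function value plus parameter-count and
    diagnostic penalties) is minimized by genetic algorithm, binary particle
    swarm, surrogate-assisted search (random forest, gradient boosted trees,
    Gaussian process) or exhaustive enumeration, alternated with a one-bit/
    two-bit downhill search with Hamming-distance niching. Pluggable fitness
    evaluators (external command adapter, synthetic epistatic landscapes, a
    toy pooled pharmacokinetic fitter on simulated concentration-time data)
    make the whole system testable without an external estimation engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    kernlab,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
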