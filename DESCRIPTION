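Package: grnmatch
Title: Gene Regulatory Network Inference by Gaussian-Process Gradient Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-step gradient-matching inference of gene regulatory
    networks from time-course expression data. Expression trajectories are
    smoothed with single-output or coregionalised multi-output Gaussian
    processes, whose analytic (or finite-difference) derivatives are matched
    against either parametric Hill-kinetics ODE right-hand sides or
    non-parametric GP regressors over candidate parent sets. Candidate
    topologies are enumerated exhaustively for the decoupled per-gene
    system, scored by BIC, combined into per-edge confidence weights via
    Schwarz-weight model averaging, and evaluated against ground-truth
    networks with precision-recall curves. Includes deterministic and
    stochastic Hill-kinetics simulators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
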