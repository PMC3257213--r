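Package: retrokin
Title: Retroactivity-Driven Off-Target Effects of Kinase Inhibitors in
    Covalent Modification Cycle Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models signaling networks built from covalent modification
    (phosphorylation) cycles in which a competitive inhibitor sequesters the
    active protein of one cycle, and quantifies the off-target steady-state
    changes this induces in non-targeted cycles purely through retroactivity
    (enzyme sequestration), without any explicit feedback connections.
    Provides exact dimensionless steady-state solvers with independent
    verification by stiff ODE integration, seeded Latin hypercube exploration
    of kinetic parameter spaces, decade sub-range perturbation sensitivity
    analysis, stimulus-response curves, and downstream amplification
    assessment, together with ready-made parameter-set and parameter-space
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
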