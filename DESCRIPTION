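Package: fatescapes
Title: Geometric Landscape Models of Cell-Fate Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing Waddington-style landscape
    models of cellular differentiation. Provides a catalogue of
    catastrophe-theory potential families (cusp, dual cusp, compactified
    elliptic umbilic) with Riemannian-metric gradient dynamics, numerical
    extraction of rest points, unstable manifolds and decision graphs,
    continuation of fold curves and detection of cusp points, location of
    heteroclinic flip bifurcations, enumeration of decision topologies,
    stochastic simulation of cell-fate proportions under signal schedules,
    and likelihood-free (ABC-SMC) fitting of landscape parameters to
    fate-proportion data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
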