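Package: tubenet
Title: Exact First-Passage Analysis and Event-Driven Simulation of
    Diffusion on Tubular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic and stochastic tools for diffusive transport on
    spatial networks built from one-dimensional tubules, such as the
    peripheral endoplasmic reticulum or fused mitochondrial networks.
    Provides exact Laplace-domain propagators for node neighborhoods and
    edges, matrix pipelines for mean and variance of first-passage times
    to absorbing nodes or partially reactive edges (including particle
    maturation), pole/residue Laplace inversion with exact
    inverse-transform samplers, and an event-driven kinetic Monte Carlo
    engine with protective domains for single- and multi-particle
    simulations, including pair encounters between mobile particles.
    Includes generators for synthetic geometries (honeycomb bands and
    patches, chains, decimated lattices), a plain-text network format,
    and a brute-force Brownian-dynamics reference simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
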