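Package: felstitch
Title: Divide-and-Conquer Free-Energy Landscapes from Restrained
    Conformational Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs two-dimensional free-energy landscapes of
    macromolecular conformational change by stitching together many short,
    independently restrained simulations.  Collective variables are
    projections onto principal components of an RMSD-fitted structure
    ensemble; each simulation is confined to a rectangular region of the
    collective-variable plane by a flat-bottom restraint with an analytic
    Cartesian force; relative region weights are obtained from sample
    counts in the pairwise region overlaps and propagated over the region
    adjacency graph; the stitched landscape applies a multiplicity
    correction for points covered by several regions.  Includes
    multi-model PDB ensemble input/output, a bead-chain Langevin sampler
    with a known equilibrium distribution for validation, and
    structure-level analyses (best-fit RMSD, representative structures,
    residue contact probabilities) that can be mapped onto the landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
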