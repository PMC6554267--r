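Package: ringconf
Title: Template-Free Conformer Generation for Macrocycles and Ring Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-stochastic conformational search for small molecules with an
    emphasis on macrocycles. Ring conformations are elaborated by physical
    movements (cross-ring bends, forced torsional twists, 180-degree flips of
    near-colinear sub-cycles, and bridge flips) over a compact valence force
    field, with explicit topological enumeration of trans-annular
    hydrogen-bond triplets for peptidic macrocycles. Conformer ensembles are
    energy windowed, redundancy pruned under graph automorphisms, and capped
    per search mode. NMR distance and torsion restraints enter the search as
    square-well penalties; ensembles can be profiled against restraint sets
    and validated against residual dipolar couplings via SVD alignment-tensor
    fits and Q-factors. Evaluation utilities include automorphism-corrected
    RMSD, success curves, and Kolmogorov-Smirnov critical differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ChemmineR,
    ChemmineOB,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
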