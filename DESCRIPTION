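Package: brushscf
Title: Lattice Self-Consistent Field Models of Bottle-Brush Polymers with
    Comb and Double-Comb Side Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical Scheutjens-Fleer self-consistent field (SF-SCF)
    modelling of cylindrical molecular bottle-brushes whose grafts are
    comb or double-comb (aggrecan-like) polymers, together with the
    matching analytical brush theory. Provides freely-jointed-chain
    propagators for branched grafts on a cylindrical shell lattice,
    self-consistent solution of the incompressibility constraint,
    radial density and end-point profiles, dead-zone theory (power-law
    inner zone matched to a shifted parabolic outer zone), brush
    moments, axial stretching forces, induced persistence lengths, and
    estimators connecting simulation to theory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
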