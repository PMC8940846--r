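Package: hcmgr
Title: Homogenized Constrained Mixture Growth and Remodeling of Arterial Walls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finite-element simulator for long-term growth and remodeling of
    arterial walls based on the homogenized constrained mixture theory.  The
    wall is modelled as a mixture of an elastin-rich matrix, smooth muscle and
    four collagen fiber families, each deposited under prestretch.  The package
    generates hexahedral meshes of cylinders and torus slices, assigns and
    iteratively calibrates non-uniform elastin prestretch fields in curved
    geometries, solves quasi-static finite-strain equilibrium with follower
    pressure loads and Robin end supports, and evolves constituent densities
    and inelastic deformations under prescribed elastin degradation and
    stress-driven collagen/smooth-muscle turnover, reproducing aneurysm
    initiation and progression scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
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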