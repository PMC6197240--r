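Package: cartdegen
Title: Mechanobiological Finite-Element Simulation of Proteoglycan Loss in
    Injured Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Cartdegen", "Maintainers", email = "maintainer@cartdegen.org",
           role = c("aut", "cre"))
Description: Simulates fixed charge density (proteoglycan) loss around
    cartilage lesions under cyclic unconfined compression.  The tissue is a
    fibril-reinforced porohyperelastic material with Donnan osmotic swelling,
    solved with a small 2D biphasic (u-p) finite-element engine.  An iterative
    degeneration algorithm depletes fixed charge density wherever cycle maxima
    of fluid velocity, deviatoric strain or maximum shear strain exceed
    thresholds, reproducing localized proteoglycan loss around cracks.
    Includes a parametric crack mesher, depth-wise composition profiles,
    inverse calibration of material parameters from stress-relaxation force
    records, and a sweep runner for parametric analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
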