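Package: sarcoXray
Title: Half-Sarcomere Monte Carlo Simulation and Meridional X-Ray
    Analysis of Actin Filament Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit Monte Carlo simulation of actomyosin
    contraction in a half sarcomere with extensible thick and thin
    filaments and strain-dependent three-state crossbridge kinetics;
    computation of meridional X-ray diffraction profiles from the
    resulting nonuniformly spaced actin monomers; and metrology plus an
    estimation pipeline that converts first and second order actin
    meridional reflections into per-filament forces and muscle tension.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
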