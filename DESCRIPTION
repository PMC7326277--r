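Package: actopull
Title: Mechanochemical Simulation of Actomyosin Networks Under Probe Pulling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained mechanochemical simulator of crosslinked
    actomyosin networks subjected to tensile force applied through a
    simulated AFM probe. Actin filaments are bead-cylinder chains with
    stretching, bending, excluded-volume, and boundary potentials; myosin
    mini-filaments and alpha-actinin crosslinkers are harmonic springs with
    force-dependent (slip, catch, stall, Brownian-ratchet) kinetics.
    Stochastic chemistry (treadmilling, binding, unbinding, motor walking)
    is simulated with the next reaction method and alternated with
    conjugate-gradient energy minimization. Includes pulling protocols,
    plain-text trajectory I/O, synthetic fixture generation, and analysis
    metrics: alignment index on filament segments or traced polylines,
    filament polarity, bundle-region F-actin fraction and recruitment rate,
    radius of gyration, and axial and radial mass distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
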