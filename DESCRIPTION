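Package: tmcoop
Title: Stochastic Thin-Filament Regulation with Tropomyosin Nearest-Neighbor Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Spatially explicit stochastic model of cardiac thin-filament
    calcium regulation in which each regulatory unit occupies one of six
    states (blocked, closed or myosin-bound tropomyosin positions, each with
    or without calcium bound to troponin C) and adjacent tropomyosins are
    coupled by an effective torsion spring acting on their azimuthal angles.
    Provides a kinetic Monte Carlo engine for a 24-unit filament with fixed
    blocked boundary units, an exact master-equation oracle for small
    filaments, steady-state force-pCa, rate-of-force-redevelopment (ktr) and
    calcium-transient-driven twitch protocols, Hill-curve analysis including
    asymmetric half-curve coefficients, twitch kinetic metrics, particle
    swarm parameter fitting, and grid-search error surfaces for
    characterizing tropomyosin mutations such as E180G and D175N.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
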