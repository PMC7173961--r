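Package: dropcenter
Title: Centering and Symmetry Breaking of Contraction Centers in
    Confined Actomyosin Droplets
Version: 0.1.0
Authors@R:
    person("Droplet", "Positioning Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and analysis tools for the positioning of actomyosin
    contraction centers in cell-sized droplets. Implements an axisymmetric
    two-phase (contracting network + viscous cytosol) Darcy model that
    computes the hydrodynamic centering force on a displaced aggregate, a
    dynamic recentering simulator, an effective stochastic clutch model of
    size-dependent symmetry breaking, an aggregate-track statistics
    pipeline (mean-squared displacement, velocity autocorrelation,
    symmetry-breaking detection, population symmetry classification), and
    fully reproducible synthetic-data generators, tied together by a
    config-driven command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
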