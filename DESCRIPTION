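Package: chemotaxsim
Title: Receptor Desensitization Model of Chemotactic Gradient Sensing and
    Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action model of ligand-induced chemoattractant receptor
    activation, homologous desensitization, internalization and re-expression,
    coupled to a two-dimensional agent-based simulator of eukaryotic cell
    migration in fixed nonlinear chemoattractant gradients. Provides
    closed-form and Runge-Kutta steady-state receptor kinetics, orientation
    vector fields for multi-unit model cells, stochastic threshold-gated
    biased persistent random walk migration, named scenario presets for
    single, opposing, angled and multi-source ligand fields, parametric
    sweeps over receptor recycling rates, track summary metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
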