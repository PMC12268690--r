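Package: stepkin
Title: Crystal Step-Growth Kinetics, Kink-Density Anisotropy, and Lattice
    Monte Carlo Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis chain for classical, step-mediated crystal
    growth of molecular crystals, built around anhydrous theophylline as the
    worked system. Provides van 't Hoff solubility thermodynamics, step
    velocity extraction from AFM-style height maps, kinetic-law fitting and
    model selection for step velocity versus concentration, terrace-step-kink
    accounting of kink formation energies from lattice bond chains,
    2D-nucleation-limited face growth rates and supersaturation-dependent
    habit classification, and seeded rejection-free kinetic Monte Carlo
    engines (restricted solid-on-solid step edge and anisotropic lattice gas)
    for step kinetics, island anisotropy, and groove self-healing
    experiments. A synthetic-data module emulates every measured input so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
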