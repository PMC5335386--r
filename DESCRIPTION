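Package: GluClear
Title: Modelling Glutamate Clearance at Hippocampal Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how astrocytic coverage shapes the lifetime of
    synaptically released glutamate. Provides a particle-based 3D Monte Carlo
    reaction-diffusion engine with triangulated synapse geometries and
    stochastic transporter kinetics, a geometry builder for simplified
    synapse/astrocyte scenes, Markov kinetic schemes with Q10 temperature
    scaling, deconvolution analysis of astrocyte transporter currents to
    recover glutamate-clearance time courses, two-photon line-scan diffusion
    analysis (tortuosity and hydrodynamic diameter), deterministic kinetic
    EPSC simulations with competitive antagonists, and seeded synthetic-data
    generators for every input class the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
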