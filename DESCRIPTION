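Package: pdtalch
Title: Potential Distribution Theory of Alchemical Coupling and Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical modelling of perturbation-energy probability densities
    for alchemical free energy calculations of molecular binding. Implements
    the multimodal Gaussian-plus-collisional (max-statistics) mixture density
    of the uncoupled state, its propagation along an alchemical path by the
    potential distribution theorem under soft-core capped perturbation
    energies and softplus alchemical potentials, construction of alchemical
    transfer models by convolution of coupling and hydration models,
    double-decoupling bookkeeping (ideal, cavity and excess terms),
    multistate reweighting (UWHAM), weighted kernel diagnostics, and
    maximum-likelihood fitting of the analytical model to multi-state
    perturbation-energy samples. A synthetic sampler draws exact samples
    from the model densities so every component is testable without
    molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
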