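Package: activejanus
Title: Interfacial Thermodynamics of Active Diffusion for Catalytic Janus
    Particles and Enzyme-Functionalized Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the enhancement of Brownian diffusion by interfacial
    chemical activity. Solves the azimuthal reaction-diffusion, heat and
    electrostatic boundary-value problems on the surface of a spherical
    catalytic Janus particle, evaluates the nondissipative (surface-tension
    based) and dissipative (entropy-production based) surface excess energy,
    maps excess energy to an active diffusivity, verifies the underlying
    inertial Langevin relations by stochastic simulation, and fits the
    interface-thickness parameter to diffusivity-versus-reaction-rate data.
    Ships parameter presets for two experimentally motivated case studies:
    nanometric catalytic Janus particles with charged substrates, and
    phospholipid vesicles with membrane-embedded ATP-hydrolyzing enzymes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
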