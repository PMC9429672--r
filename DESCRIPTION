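Package: qensdls
Title: Protein Diffusive Dynamics from Quasi-Elastic Neutron Scattering and
    Dynamic Light Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits quasi-elastic neutron scattering (QENS) spectra of protein
    solutions with resolution-convolved Lorentzian models (Voigt profiles via
    the Faddeeva function), separating solvent, apparent-elastic, internal
    jump-diffusion and Fickian center-of-mass contributions, and extracts the
    elastic incoherent structure factor (EISF) with three-site methyl-jump and
    diffusion-in-a-sphere models.  Companion tools analyse dynamic light
    scattering correlograms (Siegert single-exponential fits, q-squared decay
    rates, dilute-limit extrapolation) and interpret diffusion coefficients
    hydrodynamically: Stokes-Einstein conversions, effective hard-sphere
    volume fractions with short-time crowding factors, rotation-translation
    separation for rigid spheres, and cluster-size inversion.  A synthetic-data
    module generates instrument-realistic spectra and correlograms with known
    ground truth so every fitting stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
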