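Package: lamellaR
Title: Small-Angle Neutron Scattering Analysis of Lamellar Surfactant Phases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing small-angle neutron scattering (SANS)
    curves from lyotropic lamellar phases. Implements the Nallet
    diffuse-plus-Bragg intensity model with bounded nonlinear
    least-squares fitting, Caille parameter and Helfrich undulation
    elasticity relations, Kratky-Porod bilayer-thickness estimation from
    the ln(q^2 I) versus q^2 regression, dilution swelling-law fits
    (d = delta/phi), Porod-representation diagnostics, and a synthetic
    generator for resolution-smeared, noisy lamellar I(q) curves and
    dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
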