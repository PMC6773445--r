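Package: otomorph
Title: Hydraulic Size Control of the Zebrafish Otic Vesicle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis and biophysical modelling of hydraulic
    size control in the zebrafish otic vesicle. Provides a synthetic-data
    generator calibrated to published wild-type growth curves, kinetic
    analysis of morphometric time series (sphere-equivalent shell geometry,
    quadratic-window derivative estimation, transepithelial fluid flux,
    tissue-growth and surface-area decompositions, flux-deficit regression),
    thin-shell wall mechanics (Laplace stress, Stokes viscous relation,
    Maxwell viscoelastic response, effective-viscosity estimation with error
    propagation), a forward simulator of pressure-flux negative-feedback
    growth with puncture and drug perturbations, and the physics of a
    capillary-based pressure probe (clamped-plate deflection, capillary
    diffusion dilution, plateau extraction from pressure traces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
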