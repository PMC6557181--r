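Package: reflift
Title: Model-Independent Interfacial Profiles from Multi-Contrast Neutron Reflectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers non-solvent scattering-length-density (SLD) and
    hydration (solvent volume fraction) depth profiles at air/liquid and
    solid/liquid interfaces from specular neutron reflectivity curves
    measured at several solvent contrasts, without assuming a layer model.
    The overall layer extension is estimated by a regularized indirect
    Fourier transform of the correlation function of dSLD/dz (cubic
    B-splines, Lagrange-multiplier smoothing, point-of-inflection
    selection), and the two profiles are then reconstructed by simulated
    annealing against all contrasts simultaneously using an exact Abeles
    matrix reflectivity kernel with Gaussian resolution smearing. Includes
    a forward simulator for slab and continuous-profile systems
    (Nevot-Croce roughness), multi-run averaging, region constraints, and
    plain-text curve/profile I/O with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
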