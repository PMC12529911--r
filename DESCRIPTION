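Package: cdscs
Title: Correlation-Driven Spin-Component-Scaled MP2
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spin-component-scaled second-order Moller-Plesset perturbation
    theory driven by natural-orbital-occupancy correlation indices
    (CD-SCS-MP2). Includes a compact electronic-structure engine for small
    closed-shell molecules (Gaussian-basis integrals, restricted Hartree-Fock,
    MP2 with opposite-/same-spin resolution, relaxed and unrelaxed MP2
    densities, full CI for few-electron systems), dynamic/nondynamic
    correlation indices from natural occupancies, Coulomb-hole and radial
    intracule analysis, thermochemistry benchmark statistics (MAD, MAX, RMSD,
    WTMAD2) with a multireference screen, and exact least-absolute-deviation
    fitting of the scaling-model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
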