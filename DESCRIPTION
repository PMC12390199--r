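Package: patchyPE
Title: Monte Carlo Simulation of Polyelectrolyte Adsorption onto Patchy
    Dielectric Spheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulator of a flexible bead-spring
    polyelectrolyte interacting with a spherical particle that carries an
    axisymmetric patchy surface-charge distribution and a low-dielectric
    interior, in screened Debye-Hueckel electrolyte.  The electrostatic
    potential of the patchy sphere is evaluated as a multipole series in
    modified spherical Bessel functions and Legendre polynomials, including
    the polarization (image-charge) response of the dielectric interface.
    An analysis layer estimates critical adsorption-desorption boundaries
    (critical patch charge density and critical screening) from sigmoid fits
    of the adsorbed fraction, with block-average error estimation,
    brute-force Boltzmann-quadrature oracles for one- and two-bead chains,
    and reproducible seeded runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
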