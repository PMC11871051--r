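Package: ceisim
Title: Coulomb Explosion Imaging Simulation of Ultrafast Deplanarization in
    2-Thiouracil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates time-resolved Coulomb explosion imaging (CEI) of the
    photoexcited nucleobase 2-thiouracil. Provides a synthetic generator for
    planar ground-state geometries, C2-pyramidalized and sulfur-out-of-plane
    deformed geometries, and staged-onset excited-state trajectory ensembles;
    an instantaneous point-charge Coulomb explosion integrator yielding
    asymptotic fragment momenta; symmetry-adapted molecular-frame momentum
    representations (recoil-frame Newton plots and sum/difference-frame proton
    angular maps); and pump-probe delay-scan statistics (difference
    distributions, angular-region integrals with Poisson errors, onset-order
    detection) for quantifying the out-of-plane symmetry reduction that
    accompanies internal conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
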