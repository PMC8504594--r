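Package: mgdsim
Title: Monte Carlo Simulation of Mean Glandular Dose in Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 28 kVp tungsten-anode mammography beam (semi-empirical
    bremsstrahlung continuum with anode self-filtration and tungsten L lines),
    evaluates beam quality as the aluminum half-value layer from air kerma,
    builds compressed-breast voxel phantoms with spatially separate glandular
    and adipose compartments (or a homogeneous mixture interior), transports
    photons by Monte Carlo delta tracking with Klein-Nishina scattering under
    the kerma approximation, and reports mean glandular dose across breast
    thickness, glandular tissue ratio, and rhodium or silver filtration.
    Photon interaction coefficients for the required elements over 1-50 keV
    are packaged as plain-text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
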