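Package: axonradius
Title: Effective MR Axon Radius Mapping from Strongly Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps the effective MR axon radius from multi-shell, strongly
    diffusion-weighted MRI using closed-form log-linear two-shell estimators
    built on the zeroth-order (spherical mean) and second-order (spherical
    variance) rotationally invariant spherical harmonic (RISH) features.
    Includes restricted-diffusion cylinder signal models (Neumann and
    Van Gelderen), Rician maximum-likelihood spherical harmonic fitting,
    a Monte Carlo spin-walker simulator for axon and glia substrates with
    pulsed-gradient spin-echo signal synthesis, a synthetic multi-shell
    phantom generator, and test-retest agreement statistics (TRV, CoV,
    Lin's concordance correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
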