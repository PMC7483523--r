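Package: pscfcs
Title: Subpopulation-Selective Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for portion-selectively-chosen fluorescence correlation
    spectroscopy (pscFCS): burst analysis of two-channel single-molecule
    FRET traces, selection of molecular subpopulations by apparent FRET
    efficiency, Poisson-background replacement of unselected trace
    segments, multi-tau autocorrelation and FCS model fitting, and a
    peak-threshold sweep with quadratic extrapolation to the unbiased
    diffusion time.  Includes Stokes-Einstein conversions from diffusion
    times to molecular weights and binding stoichiometries, mass-action
    models for chaperone self-trimerization and cooperative client
    binding (monomer-trimer equilibrium, Hill isotherm, second-trimer
    binding), and a Brownian-dynamics confocal photon-trace simulator
    used to validate the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
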