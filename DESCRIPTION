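Package: ampartools
Title: Conformational Coordinates, Metadynamics Reconstruction and
    Patch-Clamp Kinetics for Two-Lobed Receptor Domain Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the extracellular domain dimers of
    ionotropic glutamate receptors and the electrophysiology of the
    channels they gate. Computes centre-of-mass conformational
    coordinates (displacement torsion and projected opening angle) for
    two-lobed clamshell dimers on single structures and trajectory frame
    series; parses PLUMED-style hills logs and reconstructs
    well-tempered metadynamics free-energy surfaces by hill summation
    and by the histogram (stationary-distribution) method, including a
    toy overdamped Langevin driver with adaptive-Gaussian deposition on
    analytic 2D potentials; measures dimer-interface geometry
    (centre-of-mass separations, marker-residue distances, contact
    footprints and their differences); and implements patch-clamp
    kinetics analyses (amplitude-weighted desensitization time
    constants, two-component Hodgkin-Huxley recovery fits,
    non-stationary fluctuation analysis, rectification indices and
    pulse-train ratios). A synthetic-data module generates rigid
    two-lobe dimers with prescribed coordinates, binomial channel-noise
    sweep ensembles, recovery series and rectifying current-voltage
    ramps so that every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    grDevices,
    MASS,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
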