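Package: phaseCT
Title: Propagation-Based Phase-Contrast CT Simulation and Single-Distance
    Phase Retrieval
Version: 0.1.0
Authors@R:
    person("phaseCT", "developers", email = "phasect@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and quantitative evaluation of
    propagation-based (in-line) phase-contrast computed tomography for
    lung-like samples. Provides seeded complex-refractive-index phantom
    generators (air vesicles in soft tissue, bone inclusion), Fresnel
    free-space propagation of projections at configurable
    sample-to-detector distances with Poisson detector noise,
    single-distance transfer-of-intensity (Paganin-type) phase retrieval
    under the homogeneous-object assumption delta/beta = gamma,
    parallel-beam filtered back-projection, Fourier-Mellin slice
    registration, and an edge/contrast metric suite (contrast-to-noise
    ratio, edge-enhancement index, sigmoid edge-steepness fitting, and an
    iterative Gaussian steepness-matching experiment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    digest,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
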