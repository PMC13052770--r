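Package: synaptrack
Title: CAR T-Cell Motility and Immune-Synapse Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying CAR T-cell migration and immune-synapse
    dynamics from live-cell imaging. Imports cell tracks from TrackMate XML
    or tidy CSV, applies quality-control filters (track length, speed caps,
    gap interpolation), computes per-track step and directionality statistics
    and mean squared displacement (MSD) with overlapping time intervals, fits
    constrained, Brownian, and persistent random-walk MSD models, selects the
    best model per track with small-sample corrected AIC (AICc), and derives
    motility parameters (persistence speed and time, random motility
    coefficient). Also quantifies immune-synapse readouts from intensity
    traces and segmentation masks: calcium F/F0 normalization and area under
    the curve, synapse contact area as mask intersection, response-speed
    regression, MTOC docking time from derivative peaks, and center-of-mass
    distance to the synapse interface. A seeded synthetic-data module
    generates tracks from each random-walk model, calcium transients, and
    mask movies with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
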