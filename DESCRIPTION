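Package: octbiofilm
Title: Biofilm Morphometrics and Friction-Limited Growth Under Laminar Flow
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for biofilm development in laminar flow
    cells imaged by optical coherence tomography (OCT). Generates synthetic
    OCT-like intensity volumes with known ground truth (tilted substratum,
    leaning-pillar microcolonies with downstream streamer filaments, Gaussian
    background noise); preprocesses volumes (rotation, substratum detection
    and flattening, cross-correlation registration); segments biofilm with a
    histogram-inflexion threshold and a removal-only outlier filter; computes
    morphometric statistics (height, thickness, solidity, streamer
    classification, substratum coverage, biovolume); evaluates plane
    Poiseuille channel hydrodynamics (wall shear stress, hydraulic diameter,
    Reynolds number) and a streamer-fluidisation viscosity estimate; and
    implements an erosion-growth balance model of friction-limited biofilm
    growth with power-law fitting of mean thickness against time and wall
    shear stress. Includes minimal multi-page TIFF input/output and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
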