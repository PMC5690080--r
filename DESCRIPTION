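Package: gantryscan
Title: Moving-Gantry Measurement of Very Large Electron-Beam Dose Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for commissioning very large horizontally directed
    electron fields at extended source-to-surface distance (total skin
    electron therapy). Transforms ionization-chamber readings acquired at
    successive gantry angles with a detector fixed on the central axis
    into the equivalent classical off-axis dose profile, via the
    gantry-angle to off-axis-position ray-line mapping and a chain of
    inverse-square and chamber directional-response corrections.
    Includes directional-response power-law fitting for thimble and
    parallel-plate (Markus) chambers, profile normalization, penumbra
    (50% point) analysis, profile comparison, CSV scan import/export, a
    command-line interface, and an analytic synthetic-beam simulator
    that provides ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
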