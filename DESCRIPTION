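Package: eitbench
Title: Evaluation Bench for Chest Electrical Impedance Tomography Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for evaluating 16-electrode
    chest electrical impedance tomography (EIT) systems. Provides a 2D
    complete-electrode-model finite-element forward solver with adjacent
    current stimulation, a breathing thorax phantom whose lung conductivity
    is coupled linearly to lung volume, GREIT-style linear time-difference
    reconstruction onto a masked 32x32 pixel grid, the standard clinical
    ventilation-distribution indices (tidal variation, volume-impedance
    linearity, right/left and ventral/dorsal fractions, global
    inhomogeneity index, center of ventilation, regional ventilation delay),
    device-agreement statistics (paired equivalence tests, Bland-Altman
    limits of agreement, repeatability variability, post-hoc power) and
    bench quality-control metrics (per-channel signal-to-noise ratio and
    drift on resistor-network recordings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
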