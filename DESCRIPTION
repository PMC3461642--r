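Package: lvrsim
Title: Regional Alveolar Mechanics and Simulation of Lung Volume Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic forward model of regional alveolar mechanics in
    homogeneous emphysema. Each alveolus follows an exponential pressure-volume
    law under a gravitational (hydrostatic) gradient of transpulmonary pressure,
    with an airway-closure rule that traps gas below the depth where
    transpulmonary pressure falls to the airway closing pressure. Layered lungs
    are integrated into regional and whole-lung residual volume (RV), total lung
    capacity (TLC) and RV/TLC, with closed-form integrals as a numerical oracle.
    Scenario presets (healthy, severe homogeneous emphysema), a two-anchor
    calibration of the deflation-limb pressure and absolute volume scale, a
    volume-reduction treatment transform for upper- versus lower-lobe therapy,
    parameter-sensitivity sweeps, and a small command-line driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
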