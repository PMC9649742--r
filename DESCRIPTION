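Package: flowspec
Title: Hydrodynamic Single-Molecule Force Spectroscopy on Microfluidic Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed hydrodynamic single-molecule
    force spectroscopy with surface-tethered beads in serially connected
    microfluidic channels. Covers equipartition force calibration from
    transverse bead fluctuations, worm-like-chain force-extension fitting,
    Evans-Ritchie dynamic force spectroscopy (rupture-force densities,
    cumulative distributions, most probable rupture force, serial-bond
    corrections and exact inverse-CDF sampling), sub-pixel bead tracking by
    Fourier cross-correlation with localized upsampling, automated tethered-
    bead selection and rupture detection from pixel-area dropout, and
    censored-exponential kinetics for toehold-mediated strand displacement.
    Includes synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    readr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
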