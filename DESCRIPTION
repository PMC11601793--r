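Package: lobulemech
Title: Micromechanical Homogenization of Hepatic Lobule Microstructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic hepatic-lobule microstructures with fat
    (steatosis) and collagen (fibrosis) deposition on a periodic rectangular
    unit cell of hexagonal lobules, and computes the bulk complex shear
    modulus (storage and loss) of liver tissue by frequency-domain
    viscoelastic finite-element homogenization with periodic boundary
    conditions. Local fat fractions are converted to complex moduli with a
    generalized self-consistent composite-sphere scheme; collagen is assigned
    as a binary elastic phase. Intended for elastography-oriented studies of
    how steatosis and fibrosis patterns shape tissue viscoelasticity at
    50-300 Hz.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
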