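Package: memfret
Title: Forster Resonance Energy Transfer Rates for Membrane-Embedded Chromophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Forster resonance energy transfer (FRET) rates between
    donor and acceptor chromophores embedded in a lipid bilayer. Implements a
    two-step protocol that combines Boltzmann-weighted ensemble photophysics
    (transition dipole strengths, unit-area spectra and their overlap) with
    membrane-frame geometry statistics (insertion depth and transition-dipole
    tilt from classical trajectories, azimuthal rotation sampling of the
    orientation factor), and a one-step protocol that pairs per-snapshot
    transition dipoles, interchromophoric distances and Gaussian line-shape
    overlaps over the full Cartesian product of donor and acceptor snapshots.
    Includes alignment diagnostics for mapping transition dipoles onto
    atomic-coordinate reference vectors, pose reduction of coordinate
    trajectories, and a synthetic-data generator covering every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
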