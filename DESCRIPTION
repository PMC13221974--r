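Package: liraseek
Title: Ligand Shape and Electrostatics Screening with Spherical-Harmonics
    Surface Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes star-shaped molecular surfaces and their electrostatic
    potentials as truncated real spherical-harmonics expansions, compares
    molecules through rotation-invariant fingerprint distances (DRIF),
    aligns hits onto queries by rotational correlation over SO(3) with
    Wigner-D transforms, and screens multi-conformer compound libraries by
    descriptor ranking. Includes readers and writers for SDF, PDB and PQR,
    Bondi van der Waals radius assignment, Gasteiger partial charges via
    Open Babel, a Coulomb point-charge surface potential model, and a
    deterministic generator of analytic and molecular test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Open Babel (obabel) for Gasteiger charge assignment
Config/testthat/edition: 3
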