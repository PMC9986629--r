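Package: rfscreen
Title: Flexible-Site Screening and Ensemble Analytics for Protein
    Thermostability Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rigidifying-flexible-sites (RFS) strategy of
    enzyme thermostabilization. Reads protein structures and coordinate
    ensembles from PDB text; computes B-factor flexibility statistics by
    secondary-structure class, surface exposure and catalytic-shell
    membership; detects and types beta-turns; triages saturation-mutagenesis
    ddG tables and vetoes evolutionarily conserved positions from a multiple
    sequence alignment; ranks candidate stabilizing mutations. Companion
    ensemble analytics cover superposition-based RMSD/RMSF, dynamic
    cross-correlation matrices, hydrogen-bond and salt-bridge frame
    occupancies, and the constraint-network-analysis transition temperature.
    Michaelis-Menten and first-order inactivation fits support enzyme
    characterization. Seeded synthetic-data generators produce every input
    the pipeline consumes, with planted ground truth for plant-and-recover
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
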