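Package: trhbkin
Title: Oxygen Binding Kinetics of Truncated Hemoglobins from Structural Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts oxygen association (kon), dissociation (koff) and affinity
    (p50) of truncated hemoglobins (trHbs) from structure-derived quantities:
    ligand-migration free-energy landscapes on 3D grids, active-site water
    hydrogen bonding, and relative oxygen binding energies. Includes an OpenDX
    scalar-field reader/writer, minimax (bottleneck) path extraction on energy
    grids, well/barrier profile detection, an Eyring multi-well kinetic model
    with birth-death splitting probabilities, multiple-sequence-alignment
    curation and active-site/tunnel residue-combination catalogs, phylogenetic
    annotation of predictions, and seeded synthetic-fixture generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
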