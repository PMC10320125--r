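Package: glowdock
Title: Swarm-Based Macromolecular Docking with Glowworm Swarm Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body and backbone-flexible docking of protein, peptide and
    DNA partners by swarm-based sampling of ligand poses over the receptor
    surface, optimized with Glowworm Swarm Optimization (GSO). Supports
    residue-restraint-guided docking (swarm filtering, restraint-oriented
    initial poses, restraint-biased scoring and model filtering), an antibody
    mode that derives restraints from CDR loops under Kabat, Chothia or IMGT
    numbering, and an explicit coarse-grained membrane mode with a planar
    bead-layer builder. Final poses are clustered per swarm, ranked by score
    and written as PDB models with a tabular report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
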