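Package: hydrosite
Title: Crystal and Trajectory Water Analysis for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ordered water molecules at protein-ligand
    interfaces. Detects conserved and bridging crystallographic waters across
    superposed structure families (Kabsch least-squares superposition, RMSD
    acceptance filtering, distance-criterion hydrogen bonds, greedy conserved-
    water clustering, apo/holo displaced-water counting) and quantifies
    hydration dynamics over molecular dynamics trajectories (solvation-shell
    populations, contact and hydrogen-bond occupancies, water residence times,
    fixed-lab-frame density grids and hydration-site extraction). Includes
    seeded synthetic generators that plant ground-truth hydration structure
    into crystal families and multi-model PDB trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
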