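Package: dualscreen
Title: Dual-Target Structure-Based Virtual Screening with Interaction
    Fingerprints and Point-Based Drug-Likeness Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-target virtual screening of docked small-molecule
    libraries. Detects and types protein-ligand interactions (hydrogen bonds,
    pi-pi stacking and T-shaped contacts, pi-alkyl, alkyl, pi-cation, pi-anion,
    pi-sulfur, halogen contacts) from receptor structures and docked poses,
    builds per-target interacting-residue fingerprints, scores binding-mode
    similarity against control ligands, applies point-based drug-likeness,
    toxicity-risk and metabolism penalties, and ranks ligands by a summative
    composite score. Includes molecular formula arithmetic, monoisotopic mass
    calculation, amide-coupling product enumeration for scaffold decoration,
    and a synthetic fixture generator (toy binding pockets with planted, typed
    interactions and ligand libraries with controlled property distributions)
    so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
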