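Package: ptmlocal
Title: Local Structural Change Analysis of Protein Phosphorylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies local versus global structural change in proteins
    upon phosphorylation. Curates pairs of intact and phosphorylated
    (SEP/TPO/PTR) chain structures from PDB files, computes windowed
    geometric indicators (Kabsch superposition RMSD, radius of gyration,
    Shrake-Rupley solvent-accessible surface area, per-residue C-alpha
    displacement) around each modification site, and segments pairs into
    groups with global, local, or no structural rearrangement. Includes a
    synthetic structure-pair generator with controlled perturbation
    scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
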