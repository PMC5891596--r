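Package: qmmlink
Title: Additive and Subtractive QM/MM Coupling with Hydrogen Link Atoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A molecular-mechanics engine and QM/MM coupling framework in the
    AMBER force-field dialect, implementing side by side the additive and the
    subtractive QM/MM energy assemblies with hydrogen link atoms, mechanical
    and electrostatic embedding, and the van der Waals, electrostatic and
    bonded link-atom correction levels (VLAC, ELAC, BLAC). Reads and writes
    AMBER prmtop topologies and a native plain-text topology format, generates
    truncated link-atom topologies automatically, merges QM-derived charges
    into full-system charge sets for mechanical embedding, and ships an
    MM-surrogate QM backend so that the exact cancellation identities between
    the coupling schemes are machine-checkable without any electronic-structure
    program. Includes a frozen-environment minimizer with harmonic distance
    restraints and RMSD/internal-coordinate comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
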