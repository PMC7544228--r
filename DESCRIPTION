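Package: g4conform
Title: Conformational Analysis of G-Quadruplex Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the conformational analysis of nucleic-acid
    G-quadruplexes from multi-model atomic coordinate files (PDB and
    mmCIF). Computes glycosidic torsion angles, endocyclic sugar torsions
    and the pseudorotation phase angle and amplitude with syn/anti and
    north/south domain classification; detects G-quartets from Hoogsteen
    hydrogen-bond geometry and derives stacking layers, columns, G-tracts,
    tetrad polarities and loop taxonomy including V-shaped loops with
    conventional/alternative and same/reverse-polarity subtyping;
    quantifies CH...O-type base-backbone contact geometry with hydrogen
    reconstruction; provides least-squares ensemble superposition and
    pairwise RMSD statistics; and includes a synthetic structure generator
    that builds furanose rings, nucleotides, G-quartets and complete mock
    quadruplexes with prescribed conformational parameters so that every
    analysis stage is testable without external downloads. Handles
    chemically modified residues (locked nucleic acid, 2'-fluoro-ribo and
    2'-fluoro-arabino guanosine) by atom-inventory chemistry detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
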