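Package: coilscan
Title: Fragment-Based Scanning of Coiled-Coil Folding Potential
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Divides a full-length protein sequence into overlapping
    fragments under a user specification (oligomer count, window length,
    overlap, optional flanking adaptor), writes prediction-ready multimer
    FASTA queries, and integrates per-fragment predicted structure models
    (PDB with pLDDT in the B-factor column, PAE matrices as JSON) into a
    per-residue feature table over the full-length sequence. Features
    include model confidence (pLDDT, PAE), parallel versus antiparallel
    bundle orientation from C-alpha inter-chain distances, and
    knobs-into-holes participation from an internal SOCKET-style detector.
    A Crick-parametric generator produces idealized coiled-coil bundles and
    complete synthetic prediction runs for testing and method development.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
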