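Package: fitmscan
Title: Topology-Aware Scanning of ER Retention Motifs and LPT Catalytic
    Triads in FITM-Family Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts endoplasmic-reticulum retrieval signals
    (cytoplasmic di-arginine motifs; C-terminal di-lysine signals and their
    proven variants) in polytopic membrane proteins, maps them onto a
    per-residue membrane topology (supplied in TOPCONS-style annotation or
    predicted from hydropathy with the positive-inside rule), annotates the
    lipid phosphatase/phosphotransferase (PAP2/LPT) catalytic-site motifs
    (C1, C2 "SGH", C3 "HxxxD/E", the FITM-specific KxN hydrophobic motif
    and luminal cysteine pairs), assembles and classifies the H-1/H-2/D-3
    (E-3) catalytic triad, predicts ER residency from motif counts, and
    aggregates motif statistics across protein families. A seeded synthetic
    membrane-protein generator with exact ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
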