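Package: tetrahelix
Title: Sequence and Structural Analysis of AGCGA-Quadruplex DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the tetrahelical DNA family built from 5'-AGCGA-3'
    repeats. Scans DNA sequences for the AGCGA-quadruplex and G-quadruplex
    consensus motifs, detects hydrogen bonds in multi-model NMR coordinate
    ensembles, classifies non-canonical base pairs (G-G N1-carbonyl
    symmetric, G-A N1-N7 carbonyl-amino, Hoogsteen G-I) and quartets (GAGA,
    GGGG, minor- and major-groove GCGC), computes helical and torsional
    parameters (rise, twist, buckle, propeller, quartet buckle, glycosidic
    chi classes, sugar pseudorotation, groove widths), converts NOE
    cross-peak volumes into classed distance restraints, and generates
    ground-truth synthetic fixtures (quartet stacks, motif-planted
    sequences, NOE volume tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    bio3d,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
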