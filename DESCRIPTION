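Package: dnallps
Title: Design and Quantitative Analysis of ssDNA/Peptide Condensates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Toolkit for studying programmable single-stranded DNA folding and
    DNA/peptide liquid-liquid phase separation. Covers ssDNA library design
    (sequence shuffling, reverse-complement palindrome screening, nested
    base-pair stability ranking, hairpin chimera assembly), FRET efficiency
    and Forster-distance analysis, circular-dichroism renaturation melting
    fits, FRAP double normalization and exponential-asymptote recovery
    kinetics, droplet-fusion aspect-ratio relaxation, coarse-grained
    bead-trajectory statistics (radius of gyration, solvent-accessible
    surface area, k-means state maps, GROMOS conformational clustering,
    stability scores, empirical FRET, interaction cutoffs and profiles,
    contact maps, nonbonded energy decomposition), and primary small-angle
    X-ray scattering analysis (Guinier, Kratky, Porod volume). A synthetic
    data module generates every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
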