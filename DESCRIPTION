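Package: memdesign
Title: Minimal-Complexity Membrane Protein Design and Biophysical Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bottom-up design of minimal-complexity integral
    membrane proteins and for the downstream biophysical calculations used to
    characterise them. Implements consensus abstraction of aligned
    transmembrane helices into a binary hydrophobic/polar (plus glycine)
    pattern, idealization into a four-residue-alphabet sequence, assembly of a
    single-chain antiparallel four-helix construct with positive-inside
    topology scoring, an idealized bundle geometry with histidine-site and
    cavity-mutation selection for heme binding, hydrodynamic mass bookkeeping
    for protein-detergent complexes (Erickson sedimentation/Stokes mass, SEC
    calibration, micelle-series extrapolation, protomer counting), equilibrium
    and kinetic heme-binding fits, one-electron Nernst potentiometry fits, and
    ABTS peroxidase turnover accounting, together with seeded synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
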