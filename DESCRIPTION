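Package: k2pcap
Title: Cap-Domain Assembly Analysis for Two-Pore-Domain Potassium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference toolkit for studying how the extracellular helical cap
    of two-pore-domain (K2P) potassium channels assembles when the canonical
    inter-subunit disulfide bridge is absent.  Provides heptad-register
    arithmetic and a sliding-window coiled-coil score with a two-Gaussian
    probability calibration for M1-P1 linker sequences, N-glycosylation
    sequon scanning, statistics for alanine-scanning oocyte screens
    (reference-normalised current and surface expression, 'conductivity'
    ratios, mechanism classification, dominant-negative suppression),
    residue-residue contact calling on multi-model PDB trajectories using a
    predefined side-chain reference carbon and a 6 Angstrom cutoff, Kabsch
    RMSD stability checks, and concordance ranking of candidate structural
    models against mutagenesis hit lists.  Synthetic-data generators (ideal
    dimeric helices with planted inter-chain distances, Gaussian-jittered
    pseudo-trajectories, simulated oocyte screens) allow the whole pipeline
    to be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
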