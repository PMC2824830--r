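Package: DNACrossover
Title: Geometry and Chirality of DNA-DNA Crossovers in Crystal Lattices
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the juxtaposition geometry of B-DNA double
    helices in crystal lattices. Reads PDB/mmCIF coordinate files, expands
    crystallographic symmetry to reconstruct packing neighbours, detects
    Watson-Crick base pairs and builds per-pair reference frames, fits best
    linear helical axes, measures signed (chiral) inter-helical crossing
    angles, and classifies each crossover as a groove-backbone self-fitted
    contact or a groove-groove juxtaposition, including detection of
    cytosine/guanine amino-phosphate anchors and divalent-cation bridges.
    Ships a synthetic-data module that builds ideal B-DNA duplexes, posed
    chiral crossovers and mock crystals so the full pipeline is testable
    without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
biocViews: StructuralPrediction, DataImport, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'utils-geometry.R' 'AllClasses.R' 'AllGenerics.R' 'accessors.R'
    'spacegroups.R' 'structure-io.R' 'crystal-symmetry.R'
    'duplex-geometry.R' 'crossover-analysis.R' 'contact-classification.R'
    'synthetic-data.R' 'pipeline.R' 'DNACrossover-package.R'
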