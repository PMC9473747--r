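Package: OligoTraj
Title: Trajectory Analysis of Amyloid Peptide Oligomerization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of short amyloidogenic peptide oligomers
    sampled by molecular dynamics or built synthetically. Provides
    multi-model PDB trajectory input/output, geometric hydrogen-bond and
    residue-contact detection, Kabsch-Sander secondary-structure
    assignment, beta-sheet pairing and oligomer topology classification
    (single sheets, bilayers, open and closed beta-barrels), gromos
    (Daura) conformational clustering on optimal-superposition Ca-RMSD,
    two-dimensional potential-of-mean-force landscapes, and a generator
    of labelled synthetic conformational ensembles of the transthyretin
    fragment TTR(105-115) and related peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Clustering
RoxygenNote: 7.3.3
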