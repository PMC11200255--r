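Package: censcore
Title: Context-Explanation-Network Scoring of Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An interpretable scoring framework for protein-ligand binding
    affinity. A context explanation network (CEN) maps a voxelized 3D
    representation of a complex to a vector of per-complex weights whose dot
    product with precalculated, max-abs-scaled physicochemical interaction
    terms (Vina/smina-style gauss, repulsion, hydrophobic, non-directional
    hydrogen bond, electrostatic, typed steric Gaussians and whole-ligand
    counts) yields a pK-scale affinity estimate decomposable term by term.
    Includes structure readers with XS atom typing, the term calculators and
    dataset-wide scaling, multi-channel voxelization with rigid augmentation,
    a configurable convolutional backbone trained by SGD with smooth-L1 loss,
    affinity-qualifier filtering and cluster-aware k-fold splitting,
    per-atom attribution of typed Gaussian contributions, weight z-score
    reports, weight-space embedding, virtual-screen metrics, and a synthetic
    complex generator for desk-scale validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
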