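Package: hcnmech
Title: Mechanical Coupling Analysis of HCN Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the mechanical coupling between the HCN
    domain, voltage-sensor domain and C-linker of hyperpolarization-activated
    cyclic nucleotide-gated (HCN) channels. Implements anisotropic network
    models (ANM) built from C-alpha bead reductions of PDB/mmCIF structures,
    linear response theory (LRT) displacement fields under four-fold
    symmetric force perturbations, k-means clustering of sampled force
    responses with elbow model selection and domain-rotation geometry,
    trajectory observables (minimum side-chain distance series and radial
    distribution functions), Boltzmann activation-curve and exponential
    kinetics fitting of patch-clamp tail-current tables, thermodynamic
    double-mutant-cycle coupling energetics, and synthetic-data generators
    with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
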