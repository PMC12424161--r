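Package: pfasbench
Title: Evaluation of Protein-PFAS Docking Predictions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking predicted protein-PFAS (per- and
    polyfluoroalkyl substance) complex structures against experimental
    references. Implements four-reference heavy-atom RMSD metrics
    (protein backbone, binding pocket, ligand, and pocket-aligned
    ligand), Kabsch superposition with explicit atom correspondence,
    symmetry-aware ligand matching, binding-pocket definition by
    distance from the ligand centroid, PFAS structural and charge
    classification (OECD, EPA OPPT CF2-CF motif, aromatic fluorine),
    dataset curation with release-date train/test splitting,
    success-rate aggregation with bootstrap confidence intervals and
    Welch tests, Top-N and hybrid pose selection, failure-mode
    decomposition, and a deterministic synthetic complex generator for
    end-to-end testing without docking engines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    igraph,
    ChemmineR,
    jsonlite
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralPrediction, Cheminformatics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structure-io.R'
    'correspondence.R'
    'curation.R'
    'evaluation-stats.R'
    'pfas-chemistry.R'
    'pfasbench-package.R'
    'pose-metrics.R'
    'pipeline.R'
    'synthetic-data.R'
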