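Package: multigex
Title: Multiverse Processing of Donor Microarray Data into Parcellated Brain
    Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts donor-level brain microarray data (probe-by-sample
    expression with stereotactic sample coordinates, in the directory layout
    of the Allen Human Brain Atlas releases) into parcellated region-by-gene
    expression matrices under a fully configurable 17-option processing
    pipeline: probe reannotation, intensity-based probe filtering, six
    probe-to-gene selection methods with three donor modes, coordinate
    correction, hemispheric mirroring, inter-areal similarity filtering,
    volumetric and surface sample-to-region assignment with distance
    tolerances, sample- and gene-wise normalization (z-score and scaled
    robust sigmoid, with matched-only and within-structure variants), and
    two sample aggregation schemes. Includes three prototypical analysis
    statistics (correlated gene expression versus distance, gene
    co-expression silhouette, regional expression PC1 versus a phenotype),
    multiverse (parameter-grid) enumeration with redundancy-aware counting,
    per-option impact scoring and ranking, PCA of estimate tables, a seeded
    synthetic-data generator with known ground truth, automated
    methods-report generation, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
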