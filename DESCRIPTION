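Package: subtypewalk
Title: Transcriptional Subtype Discovery and Driver Subnetwork Inference for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for expression-based tumor subtyping and
    subtype-specific driver network inference. Provides cross-dataset
    normalization (probe collapse, per-dataset mean centering, common-gene
    merging), knowledge-guided co-expression network construction with
    iterative clique enumeration for module discovery, consensus average-linkage
    clustering with silhouette-based core-sample selection and SigClust pairwise
    significance, a nearest shrunken centroid subtype classifier with
    cross-validation and signature-gene assignment, and random-walk-with-restart
    propagation of somatic mutation and copy-number alterations over a signaling
    network with permutation-based local and global significance. A synthetic
    cohort generator with planted modules, subtypes, driver subnetworks and
    survival differences makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
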