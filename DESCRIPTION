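Package: pfascluster
Title: Semi-Supervised Metric Learning for PFAS Bioactivity Clustering
Version: 0.1.0
Authors@R: person("PFAS", "Cluster Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A desk-scale QSAR workflow for per- and polyfluoroalkyl substances
    (PFASs): molecule-table ingest with PFAS structural filters, 2048-bit ECFP4
    fingerprints with optional binding-affinity co-descriptors, semi-supervised
    Mahalanobis metric learning from sparse activity labels, PCA/t-SNE embedding,
    k-means clustering with silhouette-based model selection, and
    maximum-common-substructure attribution with a bioactive-ratio statistic.
    Includes a seedable synthetic-data generator so every stage is testable
    without external datasets. Chemistry primitives are delegated to the RDKit
    toolkit through a bundled Python helper.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: Python (>= 3.8) with rdkit and scikit-learn on PATH as
    'python'
Config/testthat/edition: 3
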