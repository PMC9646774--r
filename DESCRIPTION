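Package: cytofl
Title: Mass-Cytometry Phenotyping and Clonality Typing of B-Cell Lymphoma Cohorts
Version: 0.1.0
Authors@R:
    person("cytofl", "maintainers", email = "cytofl@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multi-sample, multi-batch mass
    cytometry (CyTOF) cohorts of B-cell lymphoma and reactive lymph node
    samples. Provides non-negative least-squares spillover compensation,
    arcsinh transformation, control-anchored cross-batch normalization,
    kNN/Jaccard graph consensus clustering with ARI/NMI run selection,
    gap-statistic metaclustering of cluster median profiles, Shannon-entropy
    heterogeneity statistics, kappa/lambda light-chain clonality calls and
    tumor typing, exact hypergeometric cluster co-occurrence networks, and a
    synthetic cohort generator with planted population structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
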