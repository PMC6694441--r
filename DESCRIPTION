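Package: taucovnet
Title: Group-Level Tau-PET Covariance Networks with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from regional
    tau-PET uptake tables on the 90-region AAL parcellation: residualizes
    regional values for age, sex and whole-brain uptake, forms inter-regional
    Pearson correlation matrices, and binarizes them at matched sparsity.
    Computes binary-graph properties (clustering coefficient, harmonic mean
    path length, greedy-agglomerative modularity, betweenness centrality,
    degree), nonparametric group-label permutation tests across a sparsity
    grid, nodal comparisons at fixed sparsity with Benjamini-Hochberg FDR,
    ROI-level ANOVA and post-hoc contrasts, clinical-score and CSF
    correlations, and demographic table statistics. Includes a
    synthetic-cohort generator with planted covariance modules and regional
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
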