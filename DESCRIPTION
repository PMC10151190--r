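Package: lesionconn
Title: Multimodal Lesion and Connectome Prediction of Post-Stroke Deficits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating lesion anatomy, structural connectivity and
    resting-state functional connectivity to behavioural factor scores in
    chronic post-stroke aphasia. Provides a synthetic-cohort generator with
    planted ground truth; varimax-rotated principal component scoring of test
    batteries; leave-one-out cross-validated voxel-based correlational lesion
    mapping with FDR and cluster-extent correction; lesion-aware functional and
    structural connectivity feature construction; elastic-net prediction with
    nested cross-validated hyperparameter tuning and permutation significance;
    squared-error model comparison via Wilcoxon signed-rank tests;
    residual-variance analyses; nodal-degree network summaries; and seed-based
    healthy-control network overlap with Monte-Carlo cluster-extent thresholds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
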