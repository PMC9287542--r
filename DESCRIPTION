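Package: segrank
Title: Volumetric Segmentation Metrics and Significance Ranking for
    Multi-Task Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for multi-task 3D medical image
    segmentation benchmarks. Computes the Dice similarity coefficient and
    the tolerance-based normalized surface dice (NSD) on NIfTI label
    volumes, ranks competing algorithms by significance scores derived
    from pairwise one-sided Wilcoxon signed-rank tests, aggregates ranks
    hierarchically over target structures, tasks and challenge phases,
    and quantifies ranking stability with case-level bootstrapping and
    Kendall's tau. Includes a synthetic-cohort generator (ellipsoid
    phantoms, morphological perturbations, Beta-distributed metric
    tables) so the whole pipeline can be exercised without any benchmark
    data, and command-line drivers for batch evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
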