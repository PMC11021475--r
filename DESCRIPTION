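Package: umiscore
Title: Immune Signature Discovery and Single-Sample Rank Scoring for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering an immune-axis gene signature from bulk
    tumor transcriptomes and scoring it in single samples. Implements
    median-of-ratios normalization and TPM computation, PCA with gene-set
    correlation for unsupervised immune-axis identification, cohort-independent
    rank-based gene-set scoring (unidirectional and bidirectional modes, and a
    capped-rank per-cell score), classification of tumor infiltrating
    lymphocyte culture reactivity with ROC/AUC biomarker benchmarking, T cell
    receptor repertoire diversity and clonality metrics, rank-based single-cell
    type cataloging with composition tests and filtered differential
    expression, and a seeded synthetic cohort generator that emulates the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
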