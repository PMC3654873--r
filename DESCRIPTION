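Package: faime
Title: Single-Sample Pathway Mechanism Scoring with Rank-Weighted
    Expression and Prognostic Stratification
Version: 0.1.0
Authors@R:
    person("FAIME", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transforms a gene-by-sample expression matrix into
    per-sample pathway "mechanism" scores using exponentially
    rank-weighted gene expression (the FAIME transformation), derives
    directional differential-mechanism signatures between two phenotype
    groups with Benjamini-Hochberg control, quantifies directional
    signature overlap across datasets with Fisher exact and
    bootstrap-resampling empirical p-values, and stratifies an
    independent cohort by k-medoids (PAM) clustering of signature
    scores followed by Kaplan-Meier and log-rank survival analysis.
    Includes readers for GMT and NCBI gene2go geneset formats,
    coefficient-of-variation probe collapsing, and a seed-deterministic
    synthetic-data generator emulating multi-cohort tumor/normal
    designs with planted pathway deregulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
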