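Package: cnaclone
Title: Copy-Number Aberration Inference and Clonal-Origin Classification
    for Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers per-cell relative copy-number aberration (CNA) profiles
    from deep single-nucleus RNA-seq expression matrices by moving-average
    smoothing of genome-ordered, mean-centred log expression against a
    donor-balanced pooled stromal reference; detects genetic subclones by
    chromosome-arm event calling with iterative cluster merging; classifies
    cells as neoplastic from CNA-signal and CNA-correlation cutoffs and
    glial cells as pre-neoplastic when they share the tumour's initiating
    arm-level deletion but none of its additional events; and provides the
    accompanying differential-expression procedures (pairwise Wilcoxon
    cluster-specific genes and recurrent sample-versus-sample tests).
    Includes a seeded synthetic-cohort simulator with planted clonal arm
    events and ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
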