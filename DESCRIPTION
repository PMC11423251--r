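Package: pgnet
Title: Proteoglycan Signature Scoring, Cohort Stratification and Signaling
    Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis pipeline for tumor cohorts built around
    glycosylation-related gene programs. Scores gene-set activity per sample
    as the mean expression z-score relative to normal tissue, stratifies a
    cohort into signature-positive, signature-negative and gray-zone groups
    by an overexpression rule, and compares the groups with Spearman
    correlation, Wilcoxon rank-sum, Kaplan-Meier and log-rank statistics.
    Includes negative-binomial Wald differential expression with
    median-of-ratios normalization and TPM, hypergeometric
    over-representation of transcription-factor regulons and pathways, and
    PathLinker-style two-stage reconstruction of receptor-to-transcription-
    factor signaling networks from a confidence-weighted interactome via
    Yen's k-shortest loopless paths. Ships synthetic-data generators that
    emulate every input (cohorts with latent-factor-correlated scores and
    group-dependent survival, counts with planted fold changes, regulons
    with planted enrichment, interactomes with planted high-confidence
    paths) so the whole pipeline runs and is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
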