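# pgnet

Integrative transcriptomics and network modeling for tumor cohorts built
around glycosylation-related gene programs — in particular proteoglycan
(PG) signatures in lung adenocarcinoma-like settings. The package is aimed
at computational biologists who want to (i) score gene-set activity per
patient, stratify a cohort by a signature-overexpression rule and relate
the groups to survival; (ii) call differentially expressed genes from bulk
RNA-seq counts; (iii) infer the transcription factors regulating those
genes; and (iv) reconstruct the receptor-to-transcription-factor signaling
network on a confidence-weighted protein interactome. Every input can be
emulated by built-in synthetic generators with recorded ground truth, so
the entire pipeline runs — and is tested — without downloading anything.

## The statistics and algorithms

**Gene-set scoring.** Tumor expression is standardized per gene against
normal samples, `z_gj = (x_gj − mean_N(x_g)) / sd_N(x_g)`, and the score of
gene set *i* in sample *j* is the mean of the available z-scores,

```
score_ij = (1/n) Σ_{k=1..n} z_k .
```

A sample is **PG+** when at least `min_genes = 3` signature genes have
`z ≥ 3.0`, **PG−** when none does, and in the **gray zone** otherwise
(excluded from two-group comparisons). Groups are compared with Wilcoxon
rank-sum (exact tie-aware enumeration for small groups), Spearman
correlation, Kaplan–Meier curves and the log-rank test.

**Differential expression.** Genes with total count > 10 are tested with a
two-group negative-binomial Wald test: median-of-ratios size factors,
gene-wise method-of-moments dispersion (`var = μ + αμ²`), standard error
from the NB Fisher information, BH adjustment, and DEG calls at
`|log2FC| ≥ 1` and `padj ≤ 0.01` (both inclusive). TPM is provided for
abundance displays. This is deliberately lighter than DESeq2 (no dispersion
shrinkage, no outlier handling) — a documented fidelity caveat.

**Enrichment.** Transcription factors are inferred by hypergeometric
over-representation of their regulons in the DEG set (upper-tail
`P(X ≥ x)`), BH-adjusted, with a stringent `overlap ≥ 3` filter; the same
statistic powers pathway over-representation of network nodes.

**Network reconstruction.** A PathLinker-style procedure on the filtered
interactome (confidence ≥ 0.4, promiscuous hubs such as UBC removed):
each undirected edge becomes two arcs, a supersource feeds all sources
(receptors/mediators, e.g. RYK, FGFR3, PTK2, PIK3CA) and all targets
(significant TFs) feed a supersink, and Yen's algorithm returns the k
cheapest loopless paths — stage 1 unweighted with `k1 = 1000`, stage 2 on
the surviving edge union weighted by `−ln(confidence)` (edge penalty 1)
with `k2 = 50000`. Paths are ordered deterministically by
(cost, edge count, lexicographic node sequence).

## Worked example

```r
library(pgnet)

gene_sets <- synthetic_gene_sets(seed = 1)            # PG/EMT/INV/CSC sets
cohort <- simulate_cohort(gene_sets, n_tumor = 300, n_normal = 40, seed = 1)

z      <- compute_zscores(cohort$expression, cohort$normal_ids)
scores <- score_cohort(z, gene_sets)
glance(scores)
#>   n_samples n_pos n_neg n_gray frac_pos frac_neg cutoff min_genes
#> 1       300   151   126     23    0.503     0.42      3         3

tidy(spearman_rho(scores$PG, scores$EMT))
#>   method   estimate statistic  p_value  n1
#> 1 spearman    0.487   2310562 3.11e-19 300

clin <- dplyr::left_join(cohort$clinical,
                         scores[, c("sample_id", "pg_label")],
                         by = "sample_id")
tidy(logrank_test(clin, groups = c("PG+", "PG-")))
#>   method  statistic  p_value  n1  n2
#> 1 logrank      48.6 3.17e-12 126 151
```

The generator planted 48% PG+ tumors with a hazard ratio of 2; the rule
recovers 50.3% positives, the PG and EMT scores correlate through the
shared latent factor, and the log-rank test detects the planted survival
difference. `autoplot()` works on every result type (score scatter,
volcano, KM curves, enrichment bars, network diagram), and
`run_pipeline(pipeline_config(...))` executes all seven stages —
simulation, scoring, cohort statistics, differential expression, TF
inference, two-stage reconstruction, pathway enrichment — writing
TSV/GMT/JSON outputs plus a reproducibility manifest.

## Scope notes

The package implements the analysis machinery; it does not bundle TCGA,
CPTAC or any interactome release, and published cohort-specific numbers
depend on those external resources. The methods vignette
(`vignettes/pgnet-methods.Rmd`) documents the models, parameter choices,
what the synthetic generators do and do not emulate, and known limitations.
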