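---
title: "Methods: signature scoring, differential expression and signaling-network reconstruction in pgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring, differential expression and signaling-network reconstruction in pgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgnet)
options(pgnet.verbose = FALSE)
```

pgnet chains four analyses that are usually run separately: per-patient
gene-set activity scoring with cohort stratification, survival and
correlation statistics on the resulting groups, negative-binomial
differential expression, and k-shortest-paths reconstruction of a signaling
network from receptors to the transcription factors that regulate the
differentially expressed genes. This vignette documents the models, the
tunable parameters and their defaults, the synthetic-data generators used
for validation, and the numerical and design choices a maintainer should
know about.

## Gene-set scoring and stratification

Expression must arrive on log scale. For gene $g$ and tumor sample $j$,

$$z_{gj} = \frac{x_{gj} - \bar{x}^{N}_{g}}{s^{N}_{g}},$$

where the mean and the unbiased ($n-1$) standard deviation are taken over
the normal samples only. Genes whose normal-sample SD is zero get *missing*
z-scores rather than zeros: a zero would silently pull set scores toward
no-change, while a missing value drops out of the per-sample denominator.
`as_zscores()` ingests matrices standardized elsewhere (cohort portals ship
such matrices); the `provenance` field records which path produced the
numbers, because downstream values depend on it.

The score of set $i$ in sample $j$ is the arithmetic mean of the set's
available z-scores, $\mathrm{score}_{ij} = \sum_k z_k / n$, with $n$
counted per sample over genes that actually have a defined z-score. Taking
$n$ per-sample (rather than the nominal set size) was a deliberate choice
for missing data: it keeps the score an unbiased mean of what was observed.

Stratification counts the signature genes with $z \ge$ `cutoff` (default
3.0 — a conventional outlier threshold against the normal distribution of
the reference tissue; the boundary value counts). Samples with at least
`min_genes` (default 3) such genes are labelled positive, samples with none
negative, and samples with one or two fall in a gray zone. Gray-zone
samples are *retained* in score and correlation analyses but excluded from
the positive-versus-negative comparisons (Wilcoxon, survival), where an
ambiguous label would only blur the contrast. Whether correlation analyses
should also exclude them was genuinely open; the default here keeps all
patients, and `stratify_cohort()`'s output makes the restriction a
one-line filter for users who prefer it.

## Cohort statistics

* **Spearman correlation** uses average ranks with the two-sided t
  approximation (`stats::cor.test`, `exact = FALSE`).
* **Wilcoxon rank-sum** uses average ranks. When $n_a n_b \le 400$ the
  two-sided p-value is exact: a dynamic program over doubled average ranks
  (integers even under ties) counts, for every achievable rank sum, the
  number of group assignments attaining it; the two-sided p doubles the
  smaller tail and is capped at 1. Beyond that size the normal
  approximation with tie-corrected variance is used (no continuity
  correction). The exact path exists because standard implementations fall
  back to the approximation whenever ties are present, which is exactly the
  situation in small boundary-heavy score comparisons.
* **Survival** uses the Kaplan–Meier product-limit estimator and the
  two-group 1-df log-rank test via the survival package. The endpoint is
  overall survival in months with event = death; column names are
  arguments, not assumptions.
* **Multiplicity** is Benjamini–Hochberg throughout.
* **Hierarchical clustering** defaults to Euclidean distance with complete
  linkage — chosen for determinism, not claimed to reproduce any particular
  published dendrogram; rows with missing values are imputed by their own
  row mean (logged).

## Differential expression

Counts are prefiltered to genes with total count strictly greater than 10.
The phrase "more than ten reads" is ambiguous between a per-gene total and
a per-sample requirement; the total-count reading is the default and a
`mode = "any_sample"` switch covers the other.

Size factors are median-of-ratios: the reference is the per-gene geometric
mean over samples, computed on genes with no zero count, and each sample's
factor is the median of `count / reference` over those genes. The median is
taken on the ratio scale; implementations that take it on the log scale
differ only in the even-$n$ interpolation convention.

Per gene, with normalized counts $y$: group means $\hat\mu_1, \hat\mu_2$;
method-of-moments dispersion
$\hat\alpha = \max\{(\hat v - \bar\mu)/\bar\mu^2,\ 10^{-8}\}$ from the
pooled within-group variance $\hat v$ (the floor keeps the information
finite and gives the Poisson limit for under-dispersed genes);
$\log_2\mathrm{FC} = \log_2(\hat\mu_2/\hat\mu_1)$ with a pseudocount of 0.5
applied — to both the ratio and the affected group's information — only
when a group mean is zero (logged whenever it happens, so a finite fold
change is never mistaken for an observed one); the standard error comes
from the NB Fisher information of the two-group log-mean model,
$I_g = \sum_{j \in g} \mu_{gj}/(1 + \alpha\mu_{gj})$ with
$\mu_{gj} = s_j \hat\mu_g$; and the Wald p-value is two-sided normal.
`nb_wald_test(dispersion =)` accepts a known dispersion, which is also how
the Poisson-limit behavior of the formula is tested.

DEG calls use inclusive thresholds: up if $\log_2\mathrm{FC} \ge 1$ and
$p_\mathrm{adj} \le 0.01$, down symmetrically.

Relative to a full DESeq2 analysis this stage deliberately omits dispersion
shrinkage, Cook's-distance outlier replacement, extreme-count-outlier
filtering and independent filtering. Consequences worth knowing: the
gene-wise dispersion estimate is noisy at small group sizes, so the Wald
p-values are asymptotic — well calibrated from roughly 30 samples per group
(measured null Kolmogorov–Smirnov calibration improves monotonically from
n = 6 to n = 50 per group) — while ranking, fold-change recovery, power and
empirical FDR control at the `padj` threshold are already good at n = 6 + 6,
which is where the test suite exercises them.

## Enrichment

Over-representation is the one-sided upper-tail hypergeometric test: with
universe size $N$, effective set size $m$, query size $q$ and overlap $x$,
$p = P(X \ge x)$, BH-adjusted across sets. Transcription-factor inference
applies this to TF regulons with the DEG set as query and the genes tested
for differential expression as universe, then filters stringently:
$p_\mathrm{adj} \le 0.05$ *and* overlap $\ge 3$. The overlap floor exists
because a two-gene overlap can reach a tiny p-value in a small universe
while being biologically uninterpretable. The DEG query combines up- and
down-regulated genes by default (a regulon can contain both activated and
repressed targets); `deg_ids(direction =)` supports split queries.

## Network reconstruction

The interactome is undirected with confidences in $[0,1]$; duplicate pairs
collapse to the maximum confidence, self-loops are dropped. Filtering
removes edges with confidence strictly below 0.4 (the boundary is kept) and
deletes listed hub nodes (default UBC — ubiquitin interacts with nearly
everything and would short-circuit any path search).

Yen's algorithm returns the k cheapest loopless paths. Because exact cost
ties are common (unit costs, repeated confidences), the path order is made
fully deterministic: paths are ordered by total cost, then edge count, then
the lexicographic node-name sequence. Internally node indices are assigned
in sorted-name order so the lexicographic comparison is integer-wise; the
composite order is prefix-monotone, which keeps Dijkstra's label-setting
argument valid with the extended key. Cost equality uses a $10^{-12}$
tolerance. This tie rule is this package's declared contract — it is *not*
claimed to match any particular PathLinker release, whose tie behavior is
unspecified.

`pathlinker_reconstruct()` duplicates each undirected edge in both
orientations (a loopless path can use at most one orientation), attaches
zero-cost super-terminal arcs, and uses unit arc costs (unweighted mode) or
$-\ln(\mathrm{confidence}) + \ln(\mathrm{edge\ penalty})$ (weighted mode;
penalty 1 means pure log-confidence; confidence-0 edges are removed before
the transform). The returned network is the exact union of the ranked
paths; each edge carries the rank of the first path containing it (its
"ksp index").

The two-stage procedure runs stage 1 unweighted with `k1 = 1000`, takes the
union of its path edges with their original confidences as the stage-2
reference interactome, and runs stage 2 weighted with `k2 = 50000` and edge
penalty 1. The final network's nodes and edges are by construction a subset
of stage 1's. On desk-scale graphs the simple-path supply is exhausted long
before `k2`; exhaustion is reported in `glance()`, never an error.

## Synthetic-data generators

The generators emulate the *statistical structure* the analyses assume, on
an anonymous gene namespace (`G00001`, ...) chosen deliberately so nothing
implies real biology.

* **Cohort** (`simulate_cohort`): log-expression is unit-variance noise;
  each tumor has a latent severity factor $f_j \sim N(0,1)$ added with
  loading $\lambda_s$ to every gene of set $s$, which induces correlated
  set scores; a planted fraction of tumors receives an additive shift
  (default 5 normal-SD units) on the signature genes so the stratification
  rule labels them positive; normal samples are factor-free. Survival is
  exponential with hazard `baseline_hazard` × `hazard_ratio`^(planted
  positive), censored by an independent uniform variable whose horizon is
  solved numerically (uniroot on the exponential-mixture censoring
  probability) so the expected censoring fraction equals `censor_rate`.
  Defaults: 510 tumors / 58 normals and a 48% positive fraction (a
  realistic cohort scale for this tumor type), loadings 0.8 (strong but
  not deterministic coupling: unshifted tumors are mislabelled positive in
  only a few percent of cases, so planted-fraction recovery stays within a
  ±5-point band), hazard ratio 2, baseline hazard 0.02 events/month, 30%
  censoring. For two sets without the shift the scores are bivariate
  normal, so the population Spearman correlation has the closed form
  implemented in `expected_score_spearman()`:
  $\rho_S = \tfrac{6}{\pi}\arcsin(\rho_P/2)$ with
  $\rho_P = \lambda_1\lambda_2 / \sqrt{(\lambda_1^2 + 1/n_1)(\lambda_2^2 + 1/n_2)}$.
  The shift breaks bivariate normality for the signature set itself, so
  correlation-recovery checks target unshifted set pairs (or a cohort
  generated with `pg_pos_frac = 0`).
* **Counts** (`simulate_counts`): NB counts with
  $\mathrm{var} = \mu + \alpha\mu^2$, log-normal baseline means, planted
  signed log2 fold changes in condition B, multiplicative library sizes
  (default mildly variable, geometric mean 1), and gene lengths for TPM.
  Defaults mirror a small two-condition design (3 + 3 samples, 5% planted
  genes at |log2FC| = 2, dispersion 0.05).
* **Regulons** (`simulate_regulons`): decoy TFs sample targets uniformly;
  planted TFs force a Binomial(`targets_per_tf`, `enrichment_strength`)
  number of targets into the DEG set and sample the rest uniformly, so
  strength 0 coincides *exactly* with the decoy procedure (a property the
  null tests rely on) and strength 1 puts the whole regulon inside the
  DEGs.
* **Interactome** (`simulate_interactome`): one high-confidence chain
  (default confidence 0.99, three edges) from each source to a target
  through fresh intermediates, over a random background of decoy edges
  with confidences in (0.05, 0.6]. Decoy edges directly joining a source
  to a target are excluded by construction — otherwise a single decoy edge
  would always beat a multi-edge planted chain on both hop count and total
  cost, and "the planted chain ranks first" would be unachievable for any
  reconstruction method.

Every generator takes an explicit seed, uses a single RNG stream for the
whole call, restores the caller's RNG state, and records the seed in its
truth object; identical seed and parameters give bit-identical output.

What the generators do **not** emulate: real co-expression structure beyond
one latent factor, count outliers and batch effects, proteomic noise (the
protein-level entry point reuses the same scoring contract on a protein
z-score matrix), regulon overlap structure, and the degree distribution of
real interactomes. Passing tests therefore demonstrate correctness of the
statistics and algorithms under their stated models — not that any
particular biological conclusion transfers to real cohorts.

## Pipeline and problem sizes

`run_pipeline()` executes simulate → score/stratify → cohort statistics →
differential expression → TF inference → two-stage reconstruction →
pathway over-representation, writing TSV/GMT/JSON stage outputs and a
manifest (package version, seed, all parameters, per-stage counts — no
timestamps, so same-seed reruns are byte-identical). A stage failure halts
with the stage name; earlier outputs are retained.

The bundled configuration runs at desk scale — 600-gene universe, 510
tumors, 4000-gene count matrix, 40 regulons, a 26-node interactome,
k1 = 200 / k2 = 2000 — completing in seconds while leaving every stage
non-trivial. Validation problem sizes were likewise chosen to exercise each
claim where it is sharpest: exhaustive path enumeration on ≤ 8-node
digraphs, exact Wilcoxon enumeration up to rank-sum problems of size 400,
null calibration of the log-rank test over 1000 simulated cohorts, DE
effect-recovery at 6 + 6 samples and null calibration at 50 + 50.

## Known limitations

* The NB Wald test is asymptotic; at very small group sizes its raw
  p-values are anti-conservative in the tails even though fold-change
  ranking, power and empirical FDR at the calling threshold hold up. For
  publication-grade DE on real data, a shrinkage-based tool remains the
  right choice; this stage exists to make the pipeline self-contained and
  its statistics transparent.
* Yen's algorithm here is pure R, fine for desk-scale and planted-truth
  graphs; genome-scale interactomes with k in the tens of thousands would
  want a compiled implementation.
* The exact Wilcoxon dynamic program counts assignments in double
  precision; beyond the `exact_limit` guard the counts would lose exactness,
  which is why the switch is a hard size bound.
* Cox regression, GSEA-style rank tests and multi-factor DE designs are out
  of scope by design.
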