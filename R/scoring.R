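# Gene-set z-score signature scoring and cohort stratification.
#
# The score of gene set i in sample j is the arithmetic mean of the set's
# per-gene z-scores (computed against normal samples):
#   score_{i,j} = sum_k z_k / n,  over the set's genes with a defined z.
# A sample is signature-positive when at least `min_genes` signature genes
# have z >= `cutoff` (default 3.0 and 3), signature-negative when no gene
# does, and in the gray zone otherwise.

#' Standardize tumor expression against normal samples
#'
#' Computes per-gene z-scores for tumor samples relative to the mean and
#' unbiased (n-1) standard deviation of the normal samples:
#' `z_gj = (x_gj - mean_normal(x_g)) / sd_normal(x_g)`.
#' Expression must already be on log scale; this function does not
#' transform. Genes whose normal-sample SD is zero get missing (`NA`)
#' z-scores, not zeros, with one warning summarising how many.
#'
#' @param log_expression Numeric gene x sample matrix (log scale) with row
#'   and column names, containing both tumor and normal samples.
#' @param normal_ids Column names of the normal samples (at least 2).
#' @return A `pg_zscores` object: list with `values` (gene x tumor-sample
#'   z-score matrix), `normal_ids` and `provenance = "computed"`.
#' @export
#' @examples
#' x <- matrix(c(1, 2, 3, 4), 1, 4,
#'             dimnames = list("G1", c("N1", "N2", "N3", "T1")))
#' compute_zscores(x, c("N1", "N2", "N3"))$values # z = (4 - 2) / 1 = 2
compute_zscores <- function(log_expression, normal_ids) {
  x <- assert_matrix_like(log_expression, "log_expression")
  if (!all(normal_ids %in% colnames(x))) {
    pg_abort("All `normal_ids` must be columns of the expression matrix.")
  }
  if (length(normal_ids) < 2) {
    pg_abort("At least 2 normal samples are required for z-scoring.")
  }
  tumor_ids <- setdiff(colnames(x), normal_ids)
  if (length(tumor_ids) == 0) {
    pg_abort("No tumor samples left after removing normals.")
  }
  nor <- x[, normal_ids, drop = FALSE]
  m <- rowMeans(nor)
  s <- apply(nor, 1, sd)
  degenerate <- !is.finite(s) | s == 0
  if (any(degenerate)) {
    pg_warn(sprintf(
      "%d gene(s) with zero/undefined normal-sample SD: z set to missing.",
      sum(degenerate)
    ))
  }
  z <- (x[, tumor_ids, drop = FALSE] - m) / s
  z[degenerate, ] <- NA_real_
  new_zscores(z, provenance = "computed", normal_ids = normal_ids)
}

#' Wrap a pre-computed z-score matrix
#'
#' Cohort portals distribute expression already standardized against normal
#' samples; this ingests such a matrix, recording the provenance so
#' downstream reports can state which path produced the numbers.
#'
#' @param values Numeric gene x tumor-sample matrix of z-scores.
#' @param provenance Short free-text provenance tag.
#' @return A `pg_zscores` object.
#' @export
as_zscores <- function(values, provenance = "precomputed") {
  values <- assert_matrix_like(values, "values")
  if (any(is.infinite(values))) {
    pg_abort("z-score matrix must not contain infinite values.")
  }
  new_zscores(values, provenance = provenance, normal_ids = character(0))
}

new_zscores <- function(values, provenance, normal_ids) {
  structure(
    list(values = values, provenance = provenance, normal_ids = normal_ids),
    class = "pg_zscores"
  )
}

#' @export
print.pg_zscores <- function(x, ...) {
  cat(sprintf(
    "<pg_zscores> %d genes x %d tumor samples (provenance: %s)\n",
    nrow(x$values), ncol(x$values), x$provenance
  ))
  invisible(x)
}

zscore_values <- function(z) {
  if (inherits(z, "pg_zscores")) z$values else assert_matrix_like(z, "z")
}

#' Mean-z score of one gene set per sample
#'
#' `score_{i,j} = (sum_k z_k) / n` over the set's genes present in the
#' matrix with a defined z-score for sample j; `n` is the per-sample count
#' of contributing genes, so missing values shrink the denominator rather
#' than count as zero.
#'
#' @param z A `pg_zscores` object or z-score matrix.
#' @param genes Character vector of the set's gene ids.
#' @param name Optional set name used in messages.
#' @return Named numeric vector of per-sample scores (`NA` where no set
#'   gene has a defined z-score).
#' @export
gene_set_score <- function(z, genes, name = "set") {
  zm <- zscore_values(z)
  present <- intersect(genes, rownames(zm))
  if (length(present) == 0) {
    pg_abort(sprintf(
      "Gene set '%s' has no genes in the z-score matrix.", name
    ))
  }
  sub <- zm[present, , drop = FALSE]
  score <- colMeans(sub, na.rm = TRUE)
  score[colSums(!is.na(sub)) == 0] <- NA_real_
  score
}

#' Mean-z score on a protein-abundance cohort
#'
#' Identical contract to [gene_set_score()], applied to a matrix of protein
#' abundance-ratio z-scores; kept as a named entry point so pipelines make
#' explicit which molecular level a score came from.
#'
#' @inheritParams gene_set_score
#' @return Named numeric vector of per-sample scores.
#' @export
score_protein_cohort <- function(z, genes, name = "set") {
  gene_set_score(z, genes, name = name)
}

#' Score every gene set and stratify the cohort
#'
#' Computes the mean-z score for each set and assigns the signature label
#' from the overexpression rule (see [stratify_cohort()]).
#'
#' @param z A `pg_zscores` object or z-score matrix.
#' @param gene_sets Named list of gene-id vectors.
#' @param pg_set Name of the stratifying signature set.
#' @param cutoff z-score threshold for calling a gene overexpressed.
#' @param min_genes Minimum overexpressed signature genes for a positive.
#' @return A `pg_cohort_scores` tibble: `sample_id`, one score column per
#'   set, `n_over` and `pg_label` in `{"PG+", "PG-", "gray"}`; the rule
#'   parameters are kept as attributes `cutoff` and `min_genes`.
#' @export
score_cohort <- function(z, gene_sets, pg_set = "PG",
                         cutoff = 3.0, min_genes = 3) {
  zm <- zscore_values(z)
  scores <- lapply(names(gene_sets), function(nm) {
    gene_set_score(zm, gene_sets[[nm]], name = nm)
  })
  names(scores) <- names(gene_sets)
  out <- tibble(sample_id = colnames(zm))
  for (nm in names(scores)) out[[nm]] <- unname(scores[[nm]])
  strat <- stratify_cohort(zm, gene_sets[[pg_set]],
                           cutoff = cutoff, min_genes = min_genes)
  out <- left_join(out, strat, by = "sample_id")
  attr(out, "cutoff") <- cutoff
  attr(out, "min_genes") <- min_genes
  attr(out, "pg_set") <- pg_set
  class(out) <- c("pg_cohort_scores", class(out))
  out
}

#' Stratify samples by the signature overexpression rule
#'
#' Counts, per sample, the signature genes with `z >= cutoff` (the boundary
#' value counts; missing z-scores do not). Samples with at least
#' `min_genes` such genes are labelled `"PG+"`, samples with none `"PG-"`,
#' and the remainder (one or two overexpressed genes under the defaults)
#' fall in the `"gray"` zone and are excluded from two-group comparisons.
#'
#' @inheritParams score_cohort
#' @param pg_genes Character vector of signature gene ids.
#' @return Tibble with `sample_id`, `n_over` and `pg_label`.
#' @export
stratify_cohort <- function(z, pg_genes, cutoff = 3.0, min_genes = 3) {
  zm <- zscore_values(z)
  present <- intersect(pg_genes, rownames(zm))
  if (length(present) < min_genes) {
    pg_abort(sprintf(
      "Only %d signature gene(s) in the matrix; need at least min_genes = %d.",
      length(present), min_genes
    ))
  }
  if (min_genes < 1) {
    pg_abort("`min_genes` must be >= 1.")
  }
  sub <- zm[present, , drop = FALSE]
  n_miss <- sum(is.na(sub))
  if (n_miss > 0) {
    pg_log("stratify_cohort: %d missing z value(s) treated as below cutoff.",
           n_miss)
  }
  n_over <- colSums(sub >= cutoff, na.rm = TRUE)
  label <- ifelse(n_over >= min_genes, "PG+",
                  ifelse(n_over == 0, "PG-", "gray"))
  tibble(
    sample_id = colnames(zm),
    n_over = as.integer(unname(n_over)),
    pg_label = unname(label)
  )
}

#' Summary counts of a stratified cohort
#'
#' @param scores A `pg_cohort_scores` tibble from [score_cohort()].
#' @return One-row tibble: sample counts and fractions per label plus the
#'   rule parameters.
#' @method glance pg_cohort_scores
#' @export
glance.pg_cohort_scores <- function(x, ...) {
  n <- nrow(x)
  tibble(
    n_samples = n,
    n_pos = sum(x$pg_label == "PG+"),
    n_neg = sum(x$pg_label == "PG-"),
    n_gray = sum(x$pg_label == "gray"),
    frac_pos = sum(x$pg_label == "PG+") / n,
    frac_neg = sum(x$pg_label == "PG-") / n,
    cutoff = attr(x, "cutoff"),
    min_genes = attr(x, "min_genes")
  )
}
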