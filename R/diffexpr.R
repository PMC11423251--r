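# Two-group negative-binomial differential expression: count prefilter,
# median-of-ratios size factors, TPM, per-gene NB Wald test and DEG calls.
#
# Deliberately simplified relative to full DESeq2-style machinery: gene-wise
# method-of-moments dispersion with no shrinkage, no outlier replacement and
# no independent filtering. The Wald statistic is therefore asymptotic and
# best calibrated at moderate group sizes.

#' Prefilter low-count genes
#'
#' Keeps genes whose total count across all samples is strictly greater
#' than `min_total` (default: more than ten reads). The alternative
#' `"any_sample"` mode keeps genes exceeding the threshold in at least one
#' sample.
#'
#' @param counts Integer gene x sample count matrix.
#' @param min_total Count threshold (strict `>`).
#' @param mode `"total"` (row sum) or `"any_sample"` (row max).
#' @return The retained count matrix; kept/removed counts are logged.
#' @export
prefilter_genes <- function(counts, min_total = 10,
                            mode = c("total", "any_sample")) {
  mode <- match.arg(mode)
  counts <- assert_matrix_like(counts, "counts")
  if (any(counts < 0)) {
    pg_abort("Counts must be non-negative.")
  }
  stat <- if (mode == "total") rowSums(counts) else apply(counts, 1, max)
  keep <- stat > min_total
  if (!any(keep)) {
    pg_abort("No genes survive the count prefilter.")
  }
  pg_log("prefilter_genes: kept %d of %d genes (%s > %d).",
         sum(keep), length(keep), mode, min_total)
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference is the per-gene
#' geometric mean across samples, computed on genes with no zero count, and
#' each sample's factor is the median over those genes of the ratio
#' `count / reference`.
#'
#' @param counts Integer gene x sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- assert_matrix_like(counts, "counts")
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    pg_abort("No gene with all-positive counts; cannot compute size factors.")
  }
  sub <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(col) median(col / ref))
}

#' Transcripts-per-million normalization
#'
#' `rate_g = count_g / length_kb`; `TPM_gj = rate_gj / sum_g rate_gj * 1e6`,
#' so every column sums to one million.
#'
#' @param counts Integer gene x sample count matrix.
#' @param lengths Gene lengths in bases: named numeric vector or a data
#'   frame with columns `gene_id` and `length_bp`.
#' @return TPM matrix with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths) {
  counts <- assert_matrix_like(counts, "counts")
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$gene_id)
  }
  if (!all(rownames(counts) %in% names(lengths))) {
    pg_abort("Every gene needs a length.")
  }
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len) | len <= 0)) {
    pg_abort("Gene lengths must be positive.")
  }
  rate <- counts / (len / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Per-gene negative-binomial Wald test for two conditions
#'
#' For each gene: normalized group means `mu1`, `mu2`; gene-wise NB
#' dispersion `alpha` by method of moments on normalized counts
#' (`var = mu + alpha mu^2`, floored at 1e-8); `log2FC = log2(mu2 / mu1)`
#' with a pseudocount of 0.5 applied (to both the ratio and the information
#' of the affected group) only when a group mean is zero; the standard
#' error comes from the NB Fisher information of the two-group log-mean
#' model, `I_g = sum_j mu_gj / (1 + alpha mu_gj)` with `mu_gj = s_j mu_g`;
#' Wald p two-sided, BH-adjusted across tested genes.
#'
#' @param counts Integer gene x sample count matrix (prefiltered).
#' @param condition Two-level factor/character vector, one per sample;
#'   `log2FC` is second level versus first.
#' @param sf Optional size factors; computed by [size_factors()] when NULL.
#' @param dispersion Optional known dispersion (scalar or one value per
#'   gene) overriding the method-of-moments estimate; `0` gives the Poisson
#'   limit.
#' @return A `pg_de` tibble: `gene_id`, `base_mean`, `log2_fc`, `lfc_se`,
#'   `stat`, `p_value`, `padj`.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL, dispersion = NULL) {
  counts <- assert_matrix_like(counts, "counts")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) {
    pg_abort("`condition` must have exactly 2 levels.")
  }
  if (length(condition) != ncol(counts)) {
    pg_abort("One condition label per sample is required.")
  }
  if (any(table(condition) < 2)) {
    pg_abort("Each condition needs at least 2 samples.")
  }
  sf <- sf %||% size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2); n <- n1 + n2
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  v_within <- (rowSums((y[, g1, drop = FALSE] - m1)^2) +
                 rowSums((y[, g2, drop = FALSE] - m2)^2)) / (n - 2)
  mbar <- (n1 * m1 + n2 * m2) / n
  alpha <- if (is.null(dispersion)) {
    pmax((v_within - mbar) / mbar^2, 1e-8)
  } else {
    if (any(dispersion < 0)) pg_abort("`dispersion` must be >= 0.")
    pmax(rep(dispersion, length.out = nrow(counts)), 1e-8)
  }

  needs_pc <- m1 == 0 | m2 == 0
  if (any(needs_pc)) {
    pg_log("nb_wald_test: pseudocount 0.5 applied to %d gene(s) with a zero group mean.",
           sum(needs_pc))
  }
  pc <- ifelse(needs_pc, 0.5, 0)
  log2_fc <- log2((m2 + pc) / (m1 + pc))

  info_group <- function(m, sel) {
    mu <- outer(m, sf[sel])
    rowSums(mu / (1 + alpha * mu))
  }
  i1 <- info_group(m1 + pc, g1)
  i2 <- info_group(m2 + pc, g2)
  lfc_se <- sqrt(1 / i1 + 1 / i2) / log(2)
  stat <- ifelse(is.finite(lfc_se) & lfc_se > 0, log2_fc / lfc_se, 0)
  p <- 2 * pnorm(-abs(stat))

  out <- tibble(
    gene_id = rownames(counts),
    base_mean = mbar,
    log2_fc = log2_fc,
    lfc_se = lfc_se,
    stat = stat,
    p_value = p,
    padj = bh_adjust(p)
  )
  attr(out, "condition_levels") <- levels(condition)
  attr(out, "n_per_group") <- c(n1, n2)
  class(out) <- c("pg_de", class(out))
  out
}

#' Call differentially expressed genes
#'
#' Inclusive thresholds: up if `log2FC >= lfc_thresh` and
#' `padj <= padj_thresh`; down if `log2FC <= -lfc_thresh` and
#' `padj <= padj_thresh`; otherwise not significant.
#'
#' @param results A `pg_de` tibble from [nb_wald_test()].
#' @param lfc_thresh Absolute log2 fold-change threshold.
#' @param padj_thresh BH-adjusted p-value threshold.
#' @return `results` with an added `call` column in `{"up", "down", "ns"}`.
#' @export
call_degs <- function(results, lfc_thresh = 1.0, padj_thresh = 0.01) {
  if (!"padj" %in% names(results)) {
    pg_abort("`results` must carry BH-adjusted p-values (`padj`).")
  }
  sig <- !is.na(results$padj) & results$padj <= padj_thresh
  results$call <- ifelse(sig & results$log2_fc >= lfc_thresh, "up",
                         ifelse(sig & results$log2_fc <= -lfc_thresh,
                                "down", "ns"))
  attr(results, "lfc_thresh") <- lfc_thresh
  attr(results, "padj_thresh") <- padj_thresh
  if (!inherits(results, "pg_de")) {
    class(results) <- c("pg_de", class(results))
  }
  results
}

#' DEG identifiers from a called result table
#'
#' @param results A called `pg_de` tibble (see [call_degs()]).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
deg_ids <- function(results, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!"call" %in% names(results)) {
    pg_abort("Run `call_degs()` first.")
  }
  keep <- switch(direction,
    both = results$call != "ns",
    up = results$call == "up",
    down = results$call == "down"
  )
  results$gene_id[keep]
}

#' @method glance pg_de
#' @export
glance.pg_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_up = if ("call" %in% names(x)) sum(x$call == "up") else NA_integer_,
    n_down = if ("call" %in% names(x)) sum(x$call == "down") else NA_integer_,
    lfc_thresh = attr(x, "lfc_thresh") %||% NA_real_,
    padj_thresh = attr(x, "padj_thresh") %||% NA_real_
  )
}
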