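# Correlation, two-group, survival, multiplicity and clustering statistics
# used to compare signature-positive and signature-negative cohorts.

new_test_result <- function(method, statistic, p_value, estimate = NA_real_,
                            n1 = NA_integer_, n2 = NA_integer_) {
  out <- tibble(
    method = method,
    estimate = estimate,
    statistic = statistic,
    p_value = p_value,
    n1 = as.integer(n1),
    n2 = as.integer(n2)
  )
  class(out) <- c("pg_test", class(out))
  out
}

#' @method tidy pg_test
#' @export
tidy.pg_test <- function(x, ...) as_tibble(unclass(x))

#' Spearman rank correlation between two score vectors
#'
#' Tie-corrected (average-rank) Spearman rho with a two-sided p-value from
#' the t approximation. Incomplete pairs are dropped.
#'
#' @param x,y Paired numeric vectors (at least 3 complete pairs).
#' @return A `pg_test` tibble with `estimate` (rho), `statistic` (S) and
#'   `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    pg_abort("`x` and `y` must have equal length.")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    pg_abort("Need at least 3 complete pairs.")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    pg_abort("Spearman correlation is undefined for a constant vector.")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)
  )
  new_test_result(
    method = "spearman",
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    estimate = unname(ct$estimate),
    n1 = length(x)
  )
}

# exact permutation distribution of the rank-sum of group A: dynamic program
# over doubled average ranks (integers even under ties); counts stay exact
# in doubles for the sizes where the exact path is used
ranksum_exact_p <- function(r2, n_a, w2) {
  total <- sum(r2)
  dp <- matrix(0, n_a + 1, total + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- n_a
    for (k in kmax:1) {
      if (v > 0) {
        dp[k + 1, (v + 1):(total + 1)] <-
          dp[k + 1, (v + 1):(total + 1)] + dp[k, 1:(total - v + 1)]
      }
    }
  }
  counts <- dp[n_a + 1, ]
  nways <- sum(counts)
  sums <- 0:total
  p_le <- sum(counts[sums <= w2]) / nways
  p_ge <- sum(counts[sums >= w2]) / nways
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with average ranks for ties. For small problems
#' (`n_a * n_b <= exact_limit`) the two-sided p-value is computed by exact
#' enumeration of the permutation distribution (doubled smaller tail);
#' otherwise by the normal approximation with tie-corrected variance.
#'
#' @param a,b Numeric score vectors (both non-empty).
#' @param exact_limit Switch to the asymptotic path when `n_a * n_b`
#'   exceeds this.
#' @return A `pg_test` tibble; `statistic` is the rank sum W of `a`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 400) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) {
    pg_abort("Both groups must be non-empty.")
  }
  pooled <- c(a, b)
  n <- n_a + n_b
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)])
  if (length(unique(pooled)) == 1) {
    return(new_test_result("wilcoxon", w, 1, n1 = n_a, n2 = n_b))
  }
  if (n_a * n_b <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    p <- ranksum_exact_p(r2, n_a, as.integer(round(2 * w)))
  } else {
    e_w <- n_a * (n + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- n_a * n_b / 12 * ((n + 1) - tie_term)
    z <- (w - e_w) / sqrt(v_w)
    p <- 2 * pnorm(-abs(z))
  }
  new_test_result("wilcoxon", w, p, n1 = n_a, n2 = n_b)
}

check_survival_records <- function(records, time_col, event_col) {
  if (!all(c(time_col, event_col) %in% names(records))) {
    pg_abort(sprintf("`records` needs columns '%s' and '%s'.",
                     time_col, event_col))
  }
  if (any(records[[time_col]] < 0, na.rm = TRUE)) {
    pg_abort("Survival times must be non-negative.")
  }
  if (!all(records[[event_col]] %in% c(0, 1))) {
    pg_abort("Event indicators must be 0 (censored) or 1 (event).")
  }
  invisible(records)
}

#' Kaplan-Meier product-limit curves
#'
#' Wraps [survival::survfit()] over a record table: censored times drop the
#' risk set without a step; `S(0-) = 1`.
#'
#' @param records Data frame of survival records.
#' @param time_col,event_col,group_col Column names (endpoint defaults:
#'   overall survival in months, event = death). Set `group_col = NULL` for
#'   a single pooled curve.
#' @return A `pg_km` object wrapping the `survfit` fit.
#' @export
km_curve <- function(records, time_col = "os_months",
                     event_col = "os_event", group_col = "pg_label") {
  check_survival_records(records, time_col, event_col)
  if (nrow(records) < 1) {
    pg_abort("Need at least one survival record.")
  }
  d <- data.frame(
    time = records[[time_col]],
    event = records[[event_col]]
  )
  if (!is.null(group_col) && group_col %in% names(records)) {
    d$group <- as.character(records[[group_col]])
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  }
  structure(list(fit = fit, data = as_tibble(d)), class = "pg_km")
}

#' @export
print.pg_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @method tidy pg_km
#' @export
tidy.pg_km <- function(x, ...) {
  fit <- x$fit
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tibble(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with hypergeometric variance at each
#' distinct event time (via [survival::survdiff()]); invariant to swapping
#' the group labels.
#'
#' @inheritParams km_curve
#' @param groups Optional two labels to compare; default: the two labels
#'   present (samples with other labels, e.g. the gray zone, are excluded).
#' @return A `pg_test` tibble with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(records, time_col = "os_months",
                         event_col = "os_event", group_col = "pg_label",
                         groups = NULL) {
  check_survival_records(records, time_col, event_col)
  g <- as.character(records[[group_col]])
  if (!is.null(groups)) {
    keep <- g %in% groups
    records <- records[keep, , drop = FALSE]
    g <- g[keep]
  }
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    pg_abort(sprintf("Log-rank test needs exactly 2 groups, got %d.",
                     length(lev)))
  }
  if (any(table(g) == 0)) {
    pg_abort("Both groups must be non-empty.")
  }
  d <- data.frame(
    time = records[[time_col]],
    event = records[[event_col]],
    group = g
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- unname(sd_$chisq)
  new_test_result(
    method = "logrank",
    statistic = chisq,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    n1 = sum(g == lev[1]),
    n2 = sum(g == lev[2])
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Adjusted p-values, input order preserved, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    pg_abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Deterministic agglomerative hierarchical clustering
#'
#' Euclidean/complete-linkage defaults; rows with missing values are
#' imputed by their own row mean before clustering (logged). Items are the
#' rows of `mat` when `axis = "rows"`, the columns otherwise.
#'
#' @param mat Numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `pg_hclust` object: list with the `hclust` tree and `order`
#'   (leaf labels in dendrogram order).
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns"),
                                 distance = "euclidean",
                                 linkage = "complete") {
  axis <- match.arg(axis)
  mat <- assert_matrix_like(mat, "mat")
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2) {
    pg_abort("Need at least 2 items to cluster.")
  }
  n_miss <- sum(is.na(mat))
  if (n_miss > 0) {
    pg_log("hierarchical_cluster: imputing %d missing value(s) by row mean.",
           n_miss)
    rm_ <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm_[idx[, 1]]
  }
  hc <- hclust(dist(mat, method = distance), method = linkage)
  structure(
    list(hclust = hc, order = rownames(mat)[hc$order], axis = axis),
    class = "pg_hclust"
  )
}

#' @export
print.pg_hclust <- function(x, ...) {
  cat(sprintf("<pg_hclust> %d %s; leaf order: %s\n",
              length(x$order), x$axis,
              paste(head(x$order, 8), collapse = ", ")))
  invisible(x)
}
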