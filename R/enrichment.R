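# Hypergeometric over-representation: transcription-factor regulons against
# a DEG query, and pathway sets against network node sets.

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail test per set: with universe size `N`, effective set
#' size `m = |set n universe|`, query size `q` and overlap `x`, the p-value
#' is `P(X >= x)` for `X ~ Hypergeometric(N, m, q)`. P-values are
#' BH-adjusted across the tested sets. Query genes outside the universe
#' are dropped (logged); sets with no gene in the universe are dropped with
#' a warning. Results are sorted by adjusted p (ties: raw p, then set
#' name), so they do not depend on the iteration order of `sets`.
#'
#' @param query Character vector of query genes (e.g. DEGs).
#' @param sets Named list of gene sets (e.g. regulons or pathways).
#' @param universe Character vector of all testable genes.
#' @return A `pg_enrich` tibble: `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `padj` and a `genes`
#'   list-column of overlapping gene ids.
#' @export
#' @examples
#' hypergeom_overrep(c("g1", "g2", "g3", "g4"),
#'                   list(S = c("g1", "g2", "g3", "g4", "g5")),
#'                   paste0("g", 1:10)) # p = choose(5,4)/choose(10,4)
hypergeom_overrep <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    pg_abort("`universe` must be non-empty.")
  }
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    pg_log("hypergeom_overrep: %d query gene(s) outside the universe dropped.",
           length(outside))
    query <- intersect(query, universe)
  }
  eff <- lapply(sets, intersect, universe)
  empty <- lengths(eff) == 0
  if (any(empty)) {
    pg_warn(sprintf("%d set(s) with no gene in the universe dropped.",
                    sum(empty)))
    eff <- eff[!empty]
  }
  if (length(eff) == 0) {
    pg_abort("No set intersects the universe.")
  }
  n_univ <- length(universe)
  q <- length(query)
  rows <- purrr::imap_dfr(eff, function(genes, nm) {
    ov <- intersect(query, genes)
    m <- length(genes)
    x <- length(ov)
    tibble(
      set = nm,
      overlap = x,
      set_size = m,
      query_size = q,
      universe_size = n_univ,
      p_value = phyper(x - 1, m, n_univ - m, q, lower.tail = FALSE),
      genes = list(sort(ov))
    )
  })
  rows$padj <- bh_adjust(rows$p_value)
  rows <- rows |>
    select("set", "overlap", "set_size", "query_size", "universe_size",
           "p_value", "padj", "genes") |>
    arrange(.data$padj, .data$p_value, .data$set)
  class(rows) <- c("pg_enrich", class(rows))
  rows
}

#' @method glance pg_enrich
#' @export
glance.pg_enrich <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_sig_05 = sum(x$padj <= 0.05),
    min_padj = min(x$padj)
  )
}

#' Infer transcription factors whose regulons are enriched in the DEGs
#'
#' Hypergeometric over-representation of each TF's regulon in the DEG set
#' over the universe of genes tested for differential expression, followed
#' by the stringent filter: BH-adjusted `p <= padj_thresh` and overlap
#' `>= min_overlap`. The full table is retained with a `significant`
#' column; rows are ranked by adjusted p, then larger overlap.
#'
#' @param deg_set Character vector of differentially expressed genes.
#' @param regulons Named list mapping TF name to its target gene set.
#' @param universe Genes tested for differential expression.
#' @param padj_thresh BH-adjusted p-value threshold (default 0.05).
#' @param min_overlap Minimum DEG-regulon overlap (default 3).
#' @return A `pg_enrich` tibble with the added `significant` column, one
#'   row per TF.
#' @export
infer_significant_tfs <- function(deg_set, regulons, universe,
                                  padj_thresh = 0.05, min_overlap = 3) {
  res <- hypergeom_overrep(deg_set, regulons, universe)
  res$significant <- res$padj <= padj_thresh & res$overlap >= min_overlap
  res <- arrange(res, .data$padj, dplyr::desc(.data$overlap), .data$set)
  attr(res, "padj_thresh") <- padj_thresh
  attr(res, "min_overlap") <- min_overlap
  res
}

#' Significant TF names from an enrichment table
#'
#' @param x A `pg_enrich` tibble from [infer_significant_tfs()].
#' @return Character vector of significant TF names, ranked.
#' @export
significant_tfs <- function(x) {
  if (!"significant" %in% names(x)) {
    pg_abort("`x` must come from infer_significant_tfs().")
  }
  x$set[x$significant]
}
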