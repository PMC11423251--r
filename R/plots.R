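# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 aes geom_step geom_point geom_col geom_hline
#'   geom_vline geom_segment geom_text labs theme_minimal scale_color_manual
#'   coord_flip ggplot
NULL

#' Kaplan-Meier curves
#'
#' @param object A `pg_km` from [km_curve()].
#' @param ... Unused.
#' @return A ggplot of the product-limit survival curves per group.
#' @method autoplot pg_km
#' @export
autoplot.pg_km <- function(object, ...) {
  d <- tidy(object)
  # prepend S(0) = 1 per group so the step starts at the origin
  d0 <- d |>
    group_by(.data$group) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(time = 0, survival = 1)
  ggplot(bind_rows(d0, d), aes(.data$time, .data$survival,
                               color = .data$group)) +
    geom_step() +
    labs(x = "Time (months)", y = "Survival probability", color = NULL) +
    theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A called `pg_de` tibble (see [call_degs()]).
#' @param ... Unused.
#' @return A ggplot with the DEG thresholds drawn as dashed lines.
#' @method autoplot pg_de
#' @export
autoplot.pg_de <- function(object, ...) {
  if (!"call" %in% names(object)) object <- call_degs(object)
  lfc <- attr(object, "lfc_thresh") %||% 1
  pth <- attr(object, "padj_thresh") %||% 0.01
  ggplot(object, aes(.data$log2_fc, -log10(.data$padj),
                     color = .data$call)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    geom_hline(yintercept = -log10(pth), linetype = "dashed") +
    scale_color_manual(values = c(up = "#7b3294", down = "#2c7bb6",
                                  ns = "grey70")) +
    labs(x = "log2 fold change", y = "-log10 adjusted p", color = NULL) +
    theme_minimal()
}

#' Enrichment bar plot
#'
#' @param object A `pg_enrich` tibble.
#' @param n Number of top sets to show.
#' @param ... Unused.
#' @return A ggplot bar chart of `-log10(padj)` for the top sets.
#' @method autoplot pg_enrich
#' @export
autoplot.pg_enrich <- function(object, n = 15, ...) {
  d <- head(arrange(as_tibble(object), .data$padj), n)
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot(d, aes(.data$set, -log10(.data$padj))) +
    geom_col(fill = "#7b3294") +
    coord_flip() +
    labs(x = NULL, y = "-log10 adjusted p") +
    theme_minimal()
}

#' Score scatter with stratification labels
#'
#' @param object A `pg_cohort_scores` tibble from [score_cohort()].
#' @param x,y Names of the two score columns to plot (default the first
#'   two sets).
#' @param ... Unused.
#' @return A ggplot scatter of the two set scores colored by label.
#' @method autoplot pg_cohort_scores
#' @export
autoplot.pg_cohort_scores <- function(object, x = NULL, y = NULL, ...) {
  score_cols <- setdiff(names(object), c("sample_id", "n_over", "pg_label"))
  x <- x %||% score_cols[1]
  y <- y %||% score_cols[2]
  ggplot(object, aes(.data[[x]], .data[[y]], color = .data$pg_label)) +
    geom_point(size = 0.8, alpha = 0.8) +
    scale_color_manual(values = c("PG+" = "#d7191c", "PG-" = "#2c7bb6",
                                  gray = "grey60")) +
    labs(x = paste(x, "score"), y = paste(y, "score"), color = NULL) +
    theme_minimal()
}

#' Reconstructed-network diagram
#'
#' Simple deterministic circular layout; sources drawn left, targets right.
#'
#' @param object A `pg_network`.
#' @param ... Unused.
#' @return A ggplot of nodes and edges.
#' @method autoplot pg_network
#' @export
autoplot.pg_network <- function(object, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0) {
    return(ggplot() + theme_minimal() + labs(title = "empty network"))
  }
  ord <- order(nodes$role != "source", nodes$role != "intermediate",
               nodes$node)
  nodes <- nodes[ord, ]
  theta <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  layout <- tibble(node = nodes$node, role = nodes$role,
                   px = cos(theta), py = sin(theta))
  edges <- object$edges |>
    left_join(layout, by = c(node_a = "node")) |>
    rename(x = "px", y = "py") |>
    left_join(layout, by = c(node_b = "node")) |>
    rename(xend = "px", yend = "py")
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 color = "grey70", linewidth = 0.3) +
    geom_point(data = layout, aes(.data$px, .data$py, color = .data$role),
               size = 2) +
    geom_text(data = layout, aes(.data$px * 1.12, .data$py * 1.12,
                                 label = .data$node),
              size = 2.4) +
    scale_color_manual(values = c(source = "#d7191c", target = "#2c7bb6",
                                  intermediate = "grey40")) +
    labs(x = NULL, y = NULL, color = NULL) +
    theme_minimal()
}
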