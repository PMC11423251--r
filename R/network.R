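# Signaling-network reconstruction on a confidence-weighted interactome:
# interactome filtering, Yen's k-shortest loopless paths between super-
# terminals, and the two-stage (unweighted then confidence-weighted)
# receptor-to-transcription-factor procedure.
#
# Path order is fully deterministic: paths are ranked by
# (total cost, edge count, lexicographic node sequence). Node indices are
# assigned in sorted-name order so lexicographic comparison of index
# vectors equals lexicographic comparison of name sequences.

#' Filter a confidence-weighted interactome
#'
#' Removes edges with confidence strictly below `min_conf` (the boundary
#' value is kept), deletes the listed hub nodes with all incident edges,
#' and drops nodes left isolated.
#'
#' @param net A `pg_interactome` (see [as_interactome()]).
#' @param min_conf Minimum confidence kept (default 0.4).
#' @param drop_nodes Node names to delete (default the ubiquitin hub
#'   `"UBC"`, whose promiscuous interactions short-circuit path finding).
#' @return The filtered `pg_interactome`; removal counts are logged.
#' @export
filter_interactome <- function(net, min_conf = 0.4, drop_nodes = "UBC") {
  net <- as_interactome(net)
  n0 <- nrow(net)
  keep <- net$confidence >= min_conf &
    !(net$node_a %in% drop_nodes) & !(net$node_b %in% drop_nodes)
  out <- net[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    pg_abort("No edges survive the interactome filter.")
  }
  pg_log("filter_interactome: kept %d of %d edges (min_conf = %g, %d node(s) deleted).",
         nrow(out), n0, min_conf, length(drop_nodes))
  out
}

# ---- internal directed-graph machinery -------------------------------------

# digraph: nodes sorted by name; adjacency lists of (to, cost) per node
build_digraph <- function(from, to, cost) {
  nodes <- sort(unique(c(from, to)))
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  # parallel arcs collapse to the cheapest
  key <- paste(fi, ti)
  o <- order(key, cost)
  first <- !duplicated(key[o])
  fi <- fi[o][first]; ti <- ti[o][first]; cost <- cost[o][first]
  adj <- vector("list", length(nodes))
  for (i in seq_along(nodes)) adj[[i]] <- list(to = integer(0), cost = numeric(0))
  sp <- split(seq_along(fi), fi)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    idx <- sp[[nm]]
    adj[[i]] <- list(to = ti[idx], cost = cost[idx])
  }
  list(nodes = nodes, adj = adj, from = fi, to = ti, cost = cost)
}

# TRUE if path key (c1, h1, p1) precedes (c2, h2, p2); paths are integer
# vectors over lex-sorted node indices
path_lt <- function(c1, h1, p1, c2, h2, p2, tol = 1e-12) {
  if (c1 < c2 - tol) return(TRUE)
  if (c1 > c2 + tol) return(FALSE)
  if (h1 != h2) return(h1 < h2)
  m <- min(length(p1), length(p2))
  for (i in seq_len(m)) {
    if (p1[i] != p2[i]) return(p1[i] < p2[i])
  }
  length(p1) < length(p2)
}

# Dijkstra returning the (cost, hops, lex)-minimal simple path from s to t.
# banned_nodes: logical over nodes; banned: environment mapping "u>v" -> TRUE
dijkstra_best <- function(g, s, t, banned_nodes, banned) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  hops <- rep(NA_integer_, n)
  paths <- vector("list", n)
  done <- banned_nodes
  if (done[s] || done[t]) return(NULL)
  dist[s] <- 0; hops[s] <- 0L; paths[[s]] <- s
  repeat {
    u <- 0L
    for (v in which(!done & is.finite(dist))) {
      if (u == 0L ||
          path_lt(dist[v], hops[v], paths[[v]], dist[u], hops[u], paths[[u]])) {
        u <- v
      }
    }
    if (u == 0L) return(NULL)
    if (u == t) {
      return(list(cost = dist[u], path = paths[[u]]))
    }
    done[u] <- TRUE
    au <- g$adj[[u]]
    for (j in seq_along(au$to)) {
      v <- au$to[j]
      if (done[v]) next
      if (!is.null(banned) && isTRUE(banned[[paste0(u, ">", v)]])) next
      nc <- dist[u] + au$cost[j]
      np <- c(paths[[u]], v)
      nh <- hops[u] + 1L
      if (!is.finite(dist[v]) ||
          path_lt(nc, nh, np, dist[v], hops[v], paths[[v]])) {
        dist[v] <- nc; hops[v] <- nh; paths[[v]] <- np
      }
    }
  }
}

arc_cost <- function(g, u, v) {
  au <- g$adj[[u]]
  j <- match(v, au$to)
  au$cost[j]
}

# core Yen loop on an internal digraph; s, t are node indices
yen_core <- function(g, s, t, k) {
  first <- dijkstra_best(g, s, t,
                         banned_nodes = rep(FALSE, length(g$nodes)),
                         banned = NULL)
  if (is.null(first)) return(list())
  accepted <- list(first)
  cand <- list()          # candidate paths keyed by path string
  cand_keys <- character(0)
  while (length(accepted) < k) {
    prev <- accepted[[length(accepted)]]$path
    # spur from every node of the last accepted path except the terminus
    for (i in seq_len(length(prev) - 1L)) {
      spur <- prev[i]
      root <- prev[seq_len(i)]
      banned <- new.env(parent = emptyenv())
      for (acc in accepted) {
        p <- acc$path
        if (length(p) > i && identical(p[seq_len(i)], root)) {
          banned[[paste0(p[i], ">", p[i + 1L])]] <- TRUE
        }
      }
      banned_nodes <- rep(FALSE, length(g$nodes))
      if (i > 1L) banned_nodes[root[seq_len(i - 1L)]] <- TRUE
      sp <- dijkstra_best(g, spur, t, banned_nodes, banned)
      if (is.null(sp)) next
      root_cost <- 0
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          root_cost <- root_cost + arc_cost(g, prev[j], prev[j + 1L])
        }
      }
      total <- list(
        cost = root_cost + sp$cost,
        path = c(root[-length(root)], sp$path)
      )
      key <- paste(total$path, collapse = ",")
      if (!(key %in% cand_keys)) {
        cand[[length(cand) + 1L]] <- total
        cand_keys <- c(cand_keys, key)
      }
    }
    if (length(cand) == 0) break
    best <- 1L
    for (ci in seq_along(cand)) {
      if (ci == 1L) next
      a <- cand[[ci]]; b <- cand[[best]]
      if (path_lt(a$cost, length(a$path) - 1L, a$path,
                  b$cost, length(b$path) - 1L, b$path)) {
        best <- ci
      }
    }
    accepted[[length(accepted) + 1L]] <- cand[[best]]
    cand <- cand[-best]
    cand_keys <- cand_keys[-best]
  }
  accepted
}

#' Yen's k shortest loopless paths
#'
#' Returns up to `k` simple (loopless) paths from `source` to `target` in a
#' directed graph with non-negative arc costs, in the deterministic order
#' (total cost, edge count, lexicographic node sequence). Parallel arcs
#' collapse to the cheapest. Fewer than `k` simple paths means all of them
#' are returned; an unreachable target gives an empty result, not an error.
#'
#' @param edges Data frame with columns `from`, `to`, `cost` (cost >= 0).
#' @param source,target Node names, `source != target`.
#' @param k Maximum number of paths (>= 1).
#' @return Tibble with `rank`, `cost`, `n_edges` and a `path` list-column
#'   of node-name vectors.
#' @export
yen_ksp <- function(edges, source, target, k) {
  if (k < 1) pg_abort("`k` must be >= 1.")
  if (identical(source, target)) {
    pg_abort("`source` and `target` must differ.")
  }
  if (any(edges$cost < 0)) {
    pg_abort("Arc costs must be non-negative.")
  }
  g <- build_digraph(as.character(edges$from), as.character(edges$to),
                     as.numeric(edges$cost))
  s <- match(source, g$nodes)
  t <- match(target, g$nodes)
  if (is.na(s) || is.na(t)) {
    return(tibble(rank = integer(0), cost = numeric(0),
                  n_edges = integer(0), path = list()))
  }
  res <- yen_core(g, s, t, k)
  tibble(
    rank = seq_along(res),
    cost = vapply(res, `[[`, numeric(1), "cost"),
    n_edges = vapply(res, function(p) length(p$path) - 1L, integer(1)),
    path = lapply(res, function(p) g$nodes[p$path])
  )
}

#' PathLinker-style reconstruction between sources and targets
#'
#' Converts the undirected interactome to a digraph (each edge in both
#' orientations), attaches a supersource to every source and every target
#' to a supersink with zero-cost arcs, and runs Yen's algorithm between the
#' super-terminals. Arc costs are 1 in unweighted mode, and
#' `-ln(confidence) + ln(edge_penalty)` in weighted mode (confidence-0
#' edges are removed first, logged). The returned network is the exact
#' union of the ranked paths, with the super-terminals stripped.
#'
#' @param net A `pg_interactome`.
#' @param sources,targets Node names; names absent from the interactome are
#'   dropped with a warning, and targets that are also sources are removed
#'   from the targets (logged). At least one of each must remain.
#' @param k Number of paths.
#' @param weighted Use confidence-based costs (`TRUE`) or unit costs.
#' @param edge_penalty Multiplicative per-edge penalty (>= 1); 1 means
#'   costs reduce to `-ln(confidence)`.
#' @return A `pg_network`: list with `paths` (rank, cost, source, target,
#'   path), `edges` (node_a, node_b, confidence, ksp_index), `nodes`
#'   (node, role, first_rank) and `config`.
#' @export
pathlinker_reconstruct <- function(net, sources, targets, k = 1000,
                                   weighted = FALSE, edge_penalty = 1) {
  net <- as_interactome(net)
  if (edge_penalty < 1) pg_abort("`edge_penalty` must be >= 1.")
  if (k < 1) pg_abort("`k` must be >= 1.")
  nodes <- unique(c(net$node_a, net$node_b))
  miss <- setdiff(c(sources, targets), nodes)
  if (length(miss) > 0) {
    pg_warn(sprintf("Dropping %d terminal(s) absent from the interactome: %s",
                    length(miss), paste(miss, collapse = ", ")))
  }
  sources <- intersect(sources, nodes)
  targets <- intersect(targets, nodes)
  overlap <- intersect(sources, targets)
  if (length(overlap) > 0) {
    pg_log("pathlinker_reconstruct: %d node(s) both source and target removed from targets.",
           length(overlap))
    targets <- setdiff(targets, sources)
  }
  if (length(sources) == 0 || length(targets) == 0) {
    pg_abort("Need at least one source and one target present in the interactome.")
  }
  if (weighted) {
    zero <- net$confidence == 0
    if (any(zero)) {
      pg_log("pathlinker_reconstruct: removed %d zero-confidence edge(s) before log transform.",
             sum(zero))
      net <- net[!zero, , drop = FALSE]
    }
    cost <- -log(net$confidence) + log(edge_penalty)
  } else {
    cost <- rep(1, nrow(net))
  }
  ss <- "..SUPERSOURCE.."
  sk <- "..SUPERSINK.."
  edges <- tibble(
    from = c(net$node_a, net$node_b, rep(ss, length(sources)), targets),
    to = c(net$node_b, net$node_a, sources, rep(sk, length(targets))),
    cost = c(cost, cost, rep(0, length(sources) + length(targets)))
  )
  paths <- yen_ksp(edges, ss, sk, k)
  cfg <- list(sources = sources, targets = targets, k = k,
              weighted = weighted, edge_penalty = edge_penalty)
  if (nrow(paths) == 0) {
    pg_warn("No source reaches any target; returning an empty network.")
    return(new_pg_network(
      paths = tibble(rank = integer(0), cost = numeric(0),
                     source = character(0), target = character(0),
                     path = list()),
      net = net, cfg = cfg
    ))
  }
  inner <- lapply(paths$path, function(p) p[-c(1, length(p))])
  paths_tbl <- tibble(
    rank = paths$rank,
    cost = paths$cost,
    source = vapply(inner, `[`, character(1), 1),
    target = vapply(inner, function(p) p[length(p)], character(1)),
    path = inner
  )
  new_pg_network(paths_tbl, net, cfg)
}

new_pg_network <- function(paths, net, cfg) {
  # union of path edges with first-path rank ("ksp index") per edge
  if (nrow(paths) > 0) {
    edge_rows <- purrr::map2_dfr(paths$path, paths$rank, function(p, r) {
      if (length(p) < 2) return(NULL)
      tibble(
        node_a = pmin(p[-length(p)], p[-1]),
        node_b = pmax(p[-length(p)], p[-1]),
        ksp_index = r
      )
    })
    edges <- edge_rows |>
      group_by(.data$node_a, .data$node_b) |>
      summarise(ksp_index = min(.data$ksp_index), .groups = "drop") |>
      left_join(as_tibble(net)[, c("node_a", "node_b", "confidence")],
                by = c("node_a", "node_b")) |>
      select("node_a", "node_b", "confidence", "ksp_index") |>
      arrange(.data$ksp_index, .data$node_a, .data$node_b)
    node_rank <- purrr::map2_dfr(paths$path, paths$rank, function(p, r) {
      tibble(node = p, first_rank = r)
    }) |>
      group_by(.data$node) |>
      summarise(first_rank = min(.data$first_rank), .groups = "drop")
    nodes <- node_rank |>
      mutate(role = ifelse(.data$node %in% cfg$sources, "source",
                           ifelse(.data$node %in% cfg$targets, "target",
                                  "intermediate"))) |>
      select("node", "role", "first_rank") |>
      arrange(.data$first_rank, .data$node)
  } else {
    edges <- tibble(node_a = character(0), node_b = character(0),
                    confidence = numeric(0), ksp_index = integer(0))
    nodes <- tibble(node = character(0), role = character(0),
                    first_rank = integer(0))
  }
  structure(
    list(paths = paths, edges = edges, nodes = nodes, config = cfg),
    class = "pg_network"
  )
}

#' @export
print.pg_network <- function(x, ...) {
  cat(sprintf(
    "<pg_network> %d paths | %d nodes, %d edges (%s, k = %d%s)\n",
    nrow(x$paths), nrow(x$nodes), nrow(x$edges),
    if (x$config$weighted) "weighted" else "unweighted",
    x$config$k,
    if (nrow(x$paths) < x$config$k) ", paths exhausted" else ""
  ))
  invisible(x)
}

#' @method tidy pg_network
#' @export
tidy.pg_network <- function(x, ...) x$edges

#' @method glance pg_network
#' @export
glance.pg_network <- function(x, ...) {
  tibble(
    n_paths = nrow(x$paths),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    k = x$config$k,
    weighted = x$config$weighted,
    exhausted = nrow(x$paths) < x$config$k
  )
}

# interactome restricted to the edge union of a reconstructed network,
# keeping the original confidences
network_as_interactome <- function(network) {
  as_interactome(network$edges[, c("node_a", "node_b", "confidence")])
}

#' Two-stage signaling-network reconstruction
#'
#' Stage 1 runs the reconstruction unweighted (unit arc costs) with `k1`
#' paths on the filtered interactome; the union of its path edges — with
#' their original confidences — becomes the reference interactome for
#' stage 2, which reruns the reconstruction weighted by
#' `-ln(confidence)` (edge penalty 1) with `k2` paths. By construction the
#' final network's nodes and edges are a subset of stage 1's. On small
#' graphs the path supply is exhausted long before `k2`; that is reported,
#' not an error.
#'
#' @param net A filtered `pg_interactome`.
#' @param sources Source node names (receptors/mediators; defaults:
#'   RYK, FGFR3, PTK2, PIK3CA).
#' @param targets Target node names (significant transcription factors,
#'   e.g. from [infer_significant_tfs()]).
#' @param k1 Paths for the unweighted stage (default 1000).
#' @param k2 Paths for the weighted stage (default 50000).
#' @return A `pg_two_stage`: list with `stage1` and `final` (`pg_network`).
#' @export
two_stage_reconstruction <- function(net, sources = c("RYK", "FGFR3", "PTK2", "PIK3CA"),
                                     targets, k1 = 1000, k2 = 50000) {
  stage1 <- pathlinker_reconstruct(net, sources, targets,
                                   k = k1, weighted = FALSE)
  if (nrow(stage1$paths) == 0) {
    pg_warn("Stage 1 found no paths; final network is empty.")
    return(structure(list(stage1 = stage1, final = stage1),
                     class = "pg_two_stage"))
  }
  ref <- network_as_interactome(stage1)
  final <- pathlinker_reconstruct(ref, sources, targets,
                                  k = k2, weighted = TRUE, edge_penalty = 1)
  structure(list(stage1 = stage1, final = final), class = "pg_two_stage")
}

#' @export
print.pg_two_stage <- function(x, ...) {
  cat("Stage 1: "); print(x$stage1)
  cat("Final:   "); print(x$final)
  invisible(x)
}

#' @method glance pg_two_stage
#' @export
glance.pg_two_stage <- function(x, ...) {
  dplyr::bind_rows(
    mutate(glance(x$stage1), stage = "stage1"),
    mutate(glance(x$final), stage = "final")
  )
}
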