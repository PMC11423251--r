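# Independent brute-force oracles used to check the package implementations.
# These are deliberately written as plain loops / enumeration, sharing no
# code with the package internals.

options(pgnet.verbose = FALSE)

# per-gene standardization against normal columns, element by element
oracle_zscore <- function(x, normal_ids) {
  tumor_ids <- setdiff(colnames(x), normal_ids)
  out <- matrix(NA_real_, nrow(x), length(tumor_ids),
                dimnames = list(rownames(x), tumor_ids))
  for (g in rownames(x)) {
    vals <- as.numeric(x[g, normal_ids])
    m <- sum(vals) / length(vals)
    s <- sqrt(sum((vals - m)^2) / (length(vals) - 1))
    for (j in tumor_ids) {
      out[g, j] <- (x[g, j] - m) / s
    }
  }
  out
}

# arithmetic mean of available z-scores of a gene set, per sample
oracle_set_score <- function(z, genes) {
  genes <- genes[genes %in% rownames(z)]
  sapply(colnames(z), function(j) {
    vals <- z[genes, j]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
  })
}

# per-sample counting rule for the stratification labels
oracle_labels <- function(z, pg_genes, cutoff, min_genes) {
  pg_genes <- pg_genes[pg_genes %in% rownames(z)]
  sapply(colnames(z), function(j) {
    n_over <- sum(z[pg_genes, j] >= cutoff, na.rm = TRUE)
    if (n_over >= min_genes) "PG+" else if (n_over == 0) "PG-" else "gray"
  })
}

# median-of-ratios size factors, written longhand
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[keep, , drop = FALSE]
  ref <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(sub)), function(j) median(sub[, j] / ref))
}

# BH step-up: min over the tail of p_(i) * m / i
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- sapply(i:m, function(k) p[o[k]] * m / k)
    adj[o[i]] <- min(1, min(tail_vals))
  }
  adj
}

# Kaplan-Meier product-limit table by hand
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square from the event table
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (o_minus_e)^2 / v
}

# exact two-sided rank-sum p by enumerating every group assignment
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# all simple s -> t paths of a digraph by depth-first enumeration,
# sorted by (cost, edge count, lexicographic node sequence)
oracle_all_paths <- function(edges, s, t) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  cost_of <- new.env(parent = emptyenv())
  adj <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    key <- paste0(edges$from[i], ">", edges$to[i])
    old <- cost_of[[key]]
    if (is.null(old) || edges$cost[i] < old) cost_of[[key]] <- edges$cost[i]
  }
  for (key in ls(cost_of)) {
    uv <- strsplit(key, ">", fixed = TRUE)[[1]]
    adj[[uv[1]]] <- c(adj[[uv[1]]], uv[2])
  }
  found <- list()
  walk <- function(path, cost) {
    u <- path[length(path)]
    if (u == t) {
      found[[length(found) + 1]] <<- list(path = path, cost = cost)
      return()
    }
    for (v in adj[[u]]) {
      if (!(v %in% path)) {
        walk(c(path, v), cost + cost_of[[paste0(u, ">", v)]])
      }
    }
  }
  if (!is.null(adj[[s]]) || s == t) walk(s, 0)
  if (length(found) == 0) return(found)
  # lexicographic key: fixed-width sorted node indices
  lex <- vapply(found, function(p) {
    paste(sprintf("%03d", match(p$path, nodes)), collapse = ",")
  }, character(1))
  costs <- vapply(found, `[[`, numeric(1), "cost")
  lens <- vapply(found, function(p) length(p$path), integer(1))
  found[order(round(costs, 9), lens, lex)]
}

# random digraph on n nodes used in the path-oracle comparisons
random_digraph <- function(n_nodes, p_edge = 0.35, unit_costs = FALSE) {
  nodes <- sprintf("n%d", seq_len(n_nodes))
  from <- character(0); to <- character(0)
  for (u in nodes) {
    for (v in nodes) {
      if (u != v && runif(1) < p_edge) {
        from <- c(from, u); to <- c(to, v)
      }
    }
  }
  cost <- if (unit_costs) rep(1, length(from)) else runif(length(from), 0.1, 2)
  data.frame(from = from, to = to, cost = cost)
}

# md5 checksum of a file (for byte-identity comparisons)
digest_file <- function(path) unname(tools::md5sum(path))
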