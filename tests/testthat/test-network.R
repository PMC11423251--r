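test_that("interactome filtering applies the strict 0.4 boundary and hub removal", {
  net <- as_interactome(tibble::tibble(
    node_a = c("A", "A", "B", "UBC", "UBC", "C"),
    node_b = c("B", "C", "C", "D", "E", "D"),
    confidence = c(0.39, 0.40, 0.95, 0.99, 0.99, 0.7)
  ))
  filt <- filter_interactome(net)
  keys <- paste(filt$node_a, filt$node_b)
  expect_false("A B" %in% keys)          # 0.39 removed
  expect_true("A C" %in% keys)           # 0.40 kept (boundary)
  expect_false(any(grepl("UBC", keys)))  # hub and incident edges gone
  expect_equal(nrow(filt), 3)

  set.seed(51)
  # random pairs may repeat; the max-confidence collapse warning is expected
  rnd <- suppressWarnings(as_interactome(tibble::tibble(
    node_a = sprintf("n%d", sample(1:15, 40, replace = TRUE)),
    node_b = sprintf("m%d", sample(1:15, 40, replace = TRUE)),
    confidence = runif(40)
  )))
  filt2 <- filter_interactome(rnd, min_conf = 0.5, drop_nodes = "m3")
  manual <- sum(rnd$confidence >= 0.5 & rnd$node_a != "m3" & rnd$node_b != "m3")
  expect_equal(nrow(filt2), manual)
})

test_that("Yen's algorithm handles chains, diamonds and unreachable targets", {
  chain <- data.frame(from = c("a", "b"), to = c("b", "c"), cost = 1)
  res <- yen_ksp(chain, "a", "c", k = 10)
  expect_equal(nrow(res), 1)
  expect_equal(res$path[[1]], c("a", "b", "c"))

  diamond <- data.frame(from = c("a", "a", "b", "c"),
                        to = c("b", "c", "d", "d"), cost = 1)
  res2 <- yen_ksp(diamond, "a", "d", k = 5)
  expect_equal(nrow(res2), 2)
  expect_equal(res2$cost, c(2, 2))
  # lexicographic tie-break: a-b-d before a-c-d
  expect_equal(res2$path[[1]], c("a", "b", "d"))
  expect_equal(res2$path[[2]], c("a", "c", "d"))

  expect_equal(nrow(yen_ksp(chain, "c", "a", k = 3)), 0) # unreachable
  expect_error(yen_ksp(chain, "a", "a", k = 1), "differ")
})

test_that("Yen path lists equal brute-force enumeration on random digraphs", {
  set.seed(52)
  for (i in 1:40) {
    unit <- i %% 2 == 0 # alternate tie-heavy unit costs and random costs
    g <- random_digraph(sample(5:8, 1), unit_costs = unit)
    if (nrow(g) == 0) next
    nodes <- unique(c(g$from, g$to))
    if (length(nodes) < 2) next
    s <- nodes[1]; t <- nodes[length(nodes)]
    oracle <- oracle_all_paths(g, s, t)
    for (k in unique(c(1, 3, length(oracle) + 2))) {
      got <- yen_ksp(g, s, t, k = k)
      want <- oracle[seq_len(min(k, length(oracle)))]
      expect_equal(nrow(got), length(want))
      for (j in seq_along(want)) {
        expect_equal(got$path[[j]], want[[j]]$path)
        expect_equal(got$cost[j], want[[j]]$cost, tolerance = 1e-9)
      }
    }
  }
})

test_that("path costs are non-decreasing and paths simple", {
  set.seed(53)
  g <- random_digraph(8, p_edge = 0.5)
  nodes <- unique(c(g$from, g$to))
  res <- yen_ksp(g, nodes[1], nodes[length(nodes)], k = 50)
  if (nrow(res) > 1) {
    expect_true(all(diff(res$cost) >= -1e-9))
  }
  for (p in res$path) {
    expect_equal(anyDuplicated(p), 0L)
    expect_equal(p[1], nodes[1])
    expect_equal(p[length(p)], nodes[length(nodes)])
  }
})

test_that("reconstruction is the union of ranked paths with ksp indices", {
  net <- as_interactome(tibble::tibble(
    node_a = c("S", "x", "S", "y", "x"),
    node_b = c("x", "T", "y", "T", "y"),
    confidence = c(0.9, 0.9, 0.5, 0.5, 0.8)
  ))
  rec <- pathlinker_reconstruct(net, "S", "T", k = 100, weighted = TRUE)
  # cheapest: S-x-T; every edge's ksp index is its first path's rank
  expect_equal(rec$paths$path[[1]], c("S", "x", "T"))
  expect_true(all(rec$edges$ksp_index >= 1))
  edge_keys <- paste(rec$edges$node_a, rec$edges$node_b)
  path_keys <- unique(unlist(lapply(rec$paths$path, function(p) {
    paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
  })))
  expect_setequal(edge_keys, path_keys) # exact union of returned paths
  expect_false(any(grepl("SUPER", c(rec$nodes$node, edge_keys))))

  # k beyond the number of simple paths: whole terminal-connected subgraph
  rec_all <- pathlinker_reconstruct(net, "S", "T", k = 1e5)
  expect_equal(nrow(rec_all$edges), nrow(net))
  expect_true(glance(rec_all)$exhausted)
})

test_that("edge penalty 1 reduces weighted costs to -ln(confidence)", {
  net <- as_interactome(tibble::tibble(
    node_a = c("S", "x"), node_b = c("x", "T"), confidence = c(0.5, 0.25)
  ))
  rec <- pathlinker_reconstruct(net, "S", "T", k = 1, weighted = TRUE,
                                edge_penalty = 1)
  expect_equal(rec$paths$cost[1], -log(0.5) - log(0.25), tolerance = 1e-12)
})

test_that("uniform confidence powers preserve the weighted path ranking", {
  set.seed(54)
  sim <- simulate_interactome(n_nodes = 20, n_edges = 30, seed = 7)
  net <- sim$interactome
  rec1 <- pathlinker_reconstruct(net, sim$truth$sources, sim$truth$targets,
                                 k = 25, weighted = TRUE)
  net2 <- net
  net2$confidence <- net2$confidence^1.7 # cost scaling by a constant factor
  rec2 <- pathlinker_reconstruct(net2, sim$truth$sources, sim$truth$targets,
                                 k = 25, weighted = TRUE)
  expect_equal(rec1$paths$path, rec2$paths$path)
})

test_that("two-stage reconstruction nests and recovers the planted backbone", {
  sim <- simulate_interactome(seed = 9)
  filt <- filter_interactome(sim$interactome, min_conf = 0.1)
  ts <- two_stage_reconstruction(filt, sources = sim$truth$sources,
                                 targets = sim$truth$targets,
                                 k1 = 300, k2 = 600)
  expect_true(all(ts$final$nodes$node %in% ts$stage1$nodes$node))
  edge_key <- function(e) paste(e$node_a, e$node_b)
  expect_true(all(edge_key(ts$final$edges) %in% edge_key(ts$stage1$edges)))
  # the first-ranked final path is a planted chain
  p1 <- ts$final$paths$path[[1]]
  expect_true(any(vapply(sim$truth$planted_paths, identical, logical(1), p1)))
})

test_that("terminals absent from the interactome are dropped with a warning", {
  net <- as_interactome(tibble::tibble(
    node_a = "A", node_b = "B", confidence = 0.9
  ))
  expect_warning(
    rec <- pathlinker_reconstruct(net, c("A", "GHOST"), "B", k = 5),
    "absent"
  )
  expect_equal(rec$nodes$role[rec$nodes$node == "A"], "source")
  expect_error(
    suppressWarnings(pathlinker_reconstruct(net, "GHOST", "B", k = 5)),
    "at least one source"
  )
})
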