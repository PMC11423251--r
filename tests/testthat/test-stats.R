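test_that("Spearman rho hits the monotone extremes and tie-corrected values", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_rho(x, exp(x))$estimate, 1)
  expect_equal(spearman_rho(x, -x^3)$estimate, -1)

  # one tie pair: compare against cor() on average ranks
  y <- c(2, 2, 5, 1, 7, 9)
  res <- spearman_rho(x, y)
  expect_equal(res$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(21)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman_rho(exp(a), b)$estimate,
               spearman_rho(a, b)$estimate)
  expect_equal(spearman_rho(a, qlogis(plogis(b)))$estimate,
               spearman_rho(a, b)$estimate)

  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_rho(c(1, 2), c(3, 4)), "3 complete pairs")
})

test_that("Wilcoxon exact path reproduces enumeration, ties included", {
  # spec toy: 2/C(6,3) doubled
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # identical multisets -> p = 1 by symmetry
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 6))$p_value, 1)

  set.seed(22)
  for (i in 1:20) {
    a <- sample(1:8, sample(3:6, 1), replace = TRUE) # plenty of ties
    b <- sample(1:8, sample(3:6, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-12)
  }
  # no ties: agrees with the exact distribution in wilcox.test
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon asymptotic path detects large shifts", {
  set.seed(23)
  a <- rnorm(200); b <- rnorm(300, mean = 1)
  res <- wilcoxon_rank_sum(a, b)
  expect_lt(res$p_value, 1e-6)
  # and is symmetric in the group order
  expect_equal(wilcoxon_rank_sum(b, a)$p_value, res$p_value)
})

test_that("Kaplan-Meier estimator matches closed forms and a manual table", {
  rec <- tibble::tibble(os_months = 1:4, os_event = 1, pg_label = "all")
  km <- km_curve(rec)
  expect_equal(tidy(km)$survival, c(0.75, 0.5, 0.25, 0))

  rec_c <- tibble::tibble(os_months = 1:5, os_event = 0, pg_label = "all")
  expect_true(all(tidy(km_curve(rec_c))$survival == 1))

  # mixed 8-record case against the hand-computed product-limit table
  tm <- c(1, 2, 2, 3, 5, 6, 8, 9)
  ev <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km2 <- tidy(km_curve(tibble::tibble(os_months = tm, os_event = ev,
                                      pg_label = "all")))
  man <- oracle_km(tm, ev)
  got <- km2[km2$n_event > 0, c("time", "survival")]
  expect_equal(got$time, man$time)
  expect_equal(got$survival, man$surv, tolerance = 1e-12)

  expect_error(km_curve(tibble::tibble(os_months = -1, os_event = 1,
                                       pg_label = "x")), "non-negative")
})

test_that("log-rank test: zero on duplicated groups, manual oracle, relabeling", {
  base <- tibble::tibble(
    os_months = c(2, 4, 5, 7, 9), os_event = c(1, 0, 1, 1, 0)
  )
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, pg_label = "PG+"),
    dplyr::mutate(base, pg_label = "PG-")
  )
  res <- logrank_test(dup)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(24)
  toy <- tibble::tibble(
    os_months = c(3, 5, 7, 2, 12, 13, 6, 6, 9, 14),
    os_event = c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0),
    pg_label = rep(c("PG+", "PG-"), each = 5)
  )
  expect_equal(logrank_test(toy)$statistic,
               oracle_logrank(toy$os_months, toy$os_event, toy$pg_label),
               tolerance = 1e-9)
  relab <- dplyr::mutate(toy, pg_label = ifelse(pg_label == "PG+", "B", "A"))
  expect_equal(logrank_test(relab)$statistic, logrank_test(toy)$statistic)

  expect_error(logrank_test(dplyr::mutate(toy, pg_label = "one")), "2 groups")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(25)
  p <- runif(100)^2
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12)) # monotone in sorted order
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hierarchical clustering merges by the linkage arithmetic", {
  # identical columns merge first
  m <- cbind(a = c(1, 5, 2), b = c(9, 0, 4), c = c(9, 0, 4), d = c(-3, 2, 8))
  rownames(m) <- c("x", "y", "z")
  hc <- hierarchical_cluster(m, axis = "columns")
  expect_equal(sort(hc$hclust$merge[1, ]), c(-3, -2)) # b and c first

  # 1-D points {0, 1, 10, 11}: merge {0,1}, {10,11}, then join at height 11
  m2 <- matrix(c(0, 1, 10, 11), 4, 1,
               dimnames = list(c("p0", "p1", "p10", "p11"), "v"))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$hclust$height, c(1, 1, 11))
  expect_equal(sort(abs(hc2$hclust$merge[1, ])), c(1, 2))
  expect_equal(sort(abs(hc2$hclust$merge[2, ])), c(3, 4))

  # duplicated block matrix keeps blocks contiguous in the leaf order
  set.seed(26)
  blk <- matrix(rnorm(5 * 4), 5, 4)
  mat <- rbind(blk, blk + 100)
  rownames(mat) <- c(sprintf("lo%d", 1:5), sprintf("hi%d", 1:5))
  colnames(mat) <- sprintf("c%d", 1:4)
  ord <- hierarchical_cluster(mat)$order
  pos_hi <- which(startsWith(ord, "hi"))
  expect_equal(max(pos_hi) - min(pos_hi) + 1, 5L)

  expect_error(hierarchical_cluster(mat[1, , drop = FALSE]), "at least 2")
})
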