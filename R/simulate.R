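# Synthetic-data generators. Each takes an explicit `seed`, uses one global
# RNG stream for the whole call, and restores the caller's RNG state on exit,
# so identical seed + parameters give bit-identical output.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    pg_abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic gene-set collection on an anonymous gene universe
#'
#' Builds disjoint gene sets (by default a proteoglycan-like 34-gene
#' signature plus EMT, invasiveness and stemness programs) over a synthetic
#' namespace `G00001, G00002, ...`. The namespace is deliberately not HGNC:
#' the simulators emulate data *structure*, not biology.
#'
#' @param n_universe Total number of genes in the universe.
#' @param sizes Named integer vector of set sizes.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors with a `universe` attribute.
#' @export
synthetic_gene_sets <- function(n_universe = 1000,
                                sizes = c(PG = 34, EMT = 40, INV = 30, CSC = 25),
                                seed = 1) {
  if (sum(sizes) > n_universe) {
    pg_abort("Gene sets cannot exceed the universe size.")
  }
  with_seed(seed, {
    universe <- gene_names(n_universe)
    picked <- sample(universe, sum(sizes))
    sets <- split(picked, rep(names(sizes), sizes))[names(sizes)]
    attr(sets, "universe") <- universe
    sets
  })
}

#' Analytic Spearman correlation implied by the latent-factor cohort model
#'
#' Under the cohort generator, the score of set *s* for tumor *j* is
#' `lambda_s * f_j + e`, with `f_j` standard normal and `e` the mean of
#' `n_s` unit-variance gene noises. Two set scores are then bivariate normal
#' with Pearson correlation
#' `rho_P = l1*l2 / sqrt((l1^2 + 1/n1) (l2^2 + 1/n2))`, and the population
#' Spearman correlation of a bivariate normal is
#' `(6/pi) * asin(rho_P / 2)`. The value ignores the additive signature
#' shift given to planted signature-positive tumors, so it is exact for
#' unshifted set pairs (or a cohort simulated with `pg_pos_frac = 0`).
#'
#' @param lambda1,lambda2 Factor loadings of the two sets.
#' @param n1,n2 Number of genes in each set.
#' @return Expected Spearman correlation between the two set scores.
#' @export
expected_score_spearman <- function(lambda1, lambda2, n1, n2) {
  rho_p <- (lambda1 * lambda2) /
    sqrt((lambda1^2 + 1 / n1) * (lambda2^2 + 1 / n2))
  (6 / pi) * asin(rho_p / 2)
}

# uniform censoring horizon giving the requested overall censoring fraction
# for a two-group exponential survival mixture (solved deterministically)
censor_horizon <- function(rates, weights, censor_rate) {
  if (censor_rate <= 0) {
    return(Inf)
  }
  p_cens <- function(tmax) {
    sum(weights * (1 - exp(-rates * tmax)) / (rates * tmax))
  }
  uniroot(function(tm) p_cens(tm) - censor_rate,
          lower = 1e-6, upper = 1e6, tol = 1e-9)$root
}

#' Simulate a tumor/normal expression cohort with survival
#'
#' Generates log-scale expression for a gene universe where per-tumor latent
#' factors induce correlated gene-set scores, a planted fraction of tumors
#' carries an additive shift on the signature set (so the overexpression
#' rule labels them positive), and overall survival is exponential with a
#' group-dependent hazard under independent uniform censoring.
#'
#' Model, per gene `g` and tumor `j`:
#' `x_gj = sum_s lambda_s I(g in s) f_j + shift I(g in pg_set, j planted) + e`,
#' with `f_j ~ N(0,1)` and `e ~ N(0,1)`. Normal samples are factor-free pure
#' noise, so downstream z-scores are (up to estimation error) the tumor
#' values themselves.
#'
#' @param gene_sets Named list of gene-id vectors (see
#'   [synthetic_gene_sets()]); a `universe` attribute, if present, defines
#'   the full gene namespace (otherwise the union of the sets is used).
#' @param n_tumor,n_normal Sample counts (each at least 2).
#' @param factor_loadings Named loadings `lambda_s` per gene set; sets not
#'   named get loading 0. Default 0.8 for every set in `gene_sets`.
#' @param pg_set Name of the signature set that drives stratification.
#' @param pg_pos_frac Planted fraction of signature-positive tumors.
#' @param pg_shift Additive log-expression shift for planted positives on
#'   the signature genes (in normal-sample SD units).
#' @param hazard_ratio Hazard ratio of planted positives versus the rest.
#' @param baseline_hazard Events per month for planted negatives.
#' @param censor_rate Fraction of observations censored, in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `expression` (gene x sample log-expression matrix,
#'   tumors then normals), `clinical` (tibble: `sample_id`, `os_months`,
#'   `os_event`, `group`), `normal_ids`, and `truth` (planted labels, latent
#'   factors, parameters and seed).
#' @export
simulate_cohort <- function(gene_sets,
                            n_tumor = 510,
                            n_normal = 58,
                            factor_loadings = NULL,
                            pg_set = "PG",
                            pg_pos_frac = 0.48,
                            pg_shift = 5,
                            hazard_ratio = 2,
                            baseline_hazard = 0.02,
                            censor_rate = 0.3,
                            seed = 1) {
  if (length(gene_sets) == 0 || any(lengths(gene_sets) == 0)) {
    pg_abort("`gene_sets` must be non-empty sets of genes.")
  }
  if (n_tumor < 2 || n_normal < 2) {
    pg_abort("Need at least 2 tumor and 2 normal samples.")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    pg_abort("`censor_rate` must be in [0, 1).")
  }
  if (hazard_ratio <= 0 || baseline_hazard <= 0) {
    pg_abort("`hazard_ratio` and `baseline_hazard` must be positive.")
  }
  if (!pg_set %in% names(gene_sets)) {
    pg_abort(sprintf("`pg_set` '%s' is not among the gene sets.", pg_set))
  }
  assert_prob(pg_pos_frac, "pg_pos_frac")
  loadings <- setNames(rep(0.8, length(gene_sets)), names(gene_sets))
  if (!is.null(factor_loadings)) {
    if (is.null(names(factor_loadings))) {
      pg_abort("`factor_loadings` must be named by gene set.")
    }
    if (any(!is.finite(factor_loadings))) {
      pg_abort("Factor loadings must be finite.")
    }
    loadings[names(factor_loadings)] <- factor_loadings
  }
  universe <- attr(gene_sets, "universe") %||%
    sort(unique(unlist(gene_sets, use.names = FALSE)))
  n_gene <- length(universe)
  # per-gene total loading (genes in several sets sum their loadings)
  gene_loading <- setNames(numeric(n_gene), universe)
  for (s in names(gene_sets)) {
    gs <- intersect(gene_sets[[s]], universe)
    gene_loading[gs] <- gene_loading[gs] + loadings[[s]]
  }

  with_seed(seed, {
    tumor_ids <- sprintf("TUM%04d", seq_len(n_tumor))
    normal_ids <- sprintf("NORM%04d", seq_len(n_normal))
    f <- rnorm(n_tumor)
    n_pos <- round(pg_pos_frac * n_tumor)
    planted_pos <- seq_len(n_tumor) <= n_pos # tumors are exchangeable

    tum <- matrix(rnorm(n_gene * n_tumor), n_gene, n_tumor,
                  dimnames = list(universe, tumor_ids))
    tum <- tum + gene_loading %o% f
    pg_genes <- intersect(gene_sets[[pg_set]], universe)
    tum[pg_genes, planted_pos] <- tum[pg_genes, planted_pos] + pg_shift
    nor <- matrix(rnorm(n_gene * n_normal), n_gene, n_normal,
                  dimnames = list(universe, normal_ids))

    rate <- baseline_hazard * hazard_ratio^as.numeric(planted_pos)
    t_death <- rexp(n_tumor, rate = rate)
    horizon <- censor_horizon(
      rates = baseline_hazard * c(1, hazard_ratio),
      weights = c(1 - pg_pos_frac, pg_pos_frac),
      censor_rate = censor_rate
    )
    t_cens <- if (is.finite(horizon)) runif(n_tumor, 0, horizon) else Inf
    os_months <- pmin(t_death, t_cens)
    os_event <- as.integer(t_death <= t_cens)

    clinical <- tibble(
      sample_id = tumor_ids,
      os_months = os_months,
      os_event = os_event,
      group = ifelse(planted_pos, "PG+", "PG-")
    )
    list(
      expression = cbind(tum, nor),
      clinical = clinical,
      normal_ids = normal_ids,
      truth = list(
        planted_pos = setNames(planted_pos, tumor_ids),
        latent_factor = setNames(f, tumor_ids),
        factor_loadings = loadings,
        pg_set = pg_set,
        pg_pos_frac = pg_pos_frac,
        pg_shift = pg_shift,
        hazard_ratio = hazard_ratio,
        baseline_hazard = baseline_hazard,
        censor_rate = censor_rate,
        censor_horizon = horizon,
        seed = seed
      )
    )
  })
}

#' Simulate an RNA-seq count matrix with planted fold changes
#'
#' Negative-binomial counts (`var = mu + dispersion * mu^2`) for two
#' conditions, with a chosen subset of genes shifted in condition B by a
#' planted log2 fold change and per-sample library-size factors applied
#' multiplicatively.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition (at least 3), length 1 or 2.
#' @param planted_frac Fraction of genes given a planted fold change (half
#'   up, half down).
#' @param planted_lfc Absolute planted log2 fold change.
#' @param dispersion NB dispersion `alpha >= 0`.
#' @param library_sizes Optional per-sample scale factors (length = total
#'   samples); default mildly variable log-normal factors with geometric
#'   mean 1.
#' @param mean_log,sd_log Log-normal parameters for baseline gene means.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix), `condition` (factor A/B),
#'   `gene_lengths` (tibble: gene_id, length_bp) and `truth` (planted ids
#'   with signed lfc, dispersion, library sizes, seed).
#' @export
simulate_counts <- function(n_genes = 10000,
                            n_per_group = c(3, 3),
                            planted_frac = 0.05,
                            planted_lfc = 2,
                            dispersion = 0.05,
                            library_sizes = NULL,
                            mean_log = 4,
                            sd_log = 1.5,
                            seed = 1) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  if (any(n_per_group < 3)) {
    pg_abort("Need at least 3 samples per condition.")
  }
  if (dispersion < 0) {
    pg_abort("`dispersion` must be >= 0.")
  }
  assert_prob(planted_frac, "planted_frac")
  if (!is.finite(planted_lfc)) {
    pg_abort("`planted_lfc` must be finite.")
  }
  n_samp <- sum(n_per_group)
  with_seed(seed, {
    genes <- gene_names(n_genes)
    samples <- sprintf("S%02d", seq_len(n_samp))
    condition <- factor(rep(c("A", "B"), n_per_group))
    mu0 <- rlnorm(n_genes, meanlog = mean_log, sdlog = sd_log)
    if (any(mu0 < 0)) pg_abort("Negative mean parameter.")
    if (is.null(library_sizes)) {
      library_sizes <- rlnorm(n_samp, 0, 0.2)
      library_sizes <- library_sizes / exp(mean(log(library_sizes)))
    } else if (length(library_sizes) != n_samp || any(library_sizes <= 0)) {
      pg_abort("`library_sizes` must be positive, one per sample.")
    }
    n_deg <- round(planted_frac * n_genes)
    lfc <- numeric(n_genes)
    if (n_deg > 0) {
      idx <- sample.int(n_genes, n_deg)
      sgn <- rep(c(1, -1), length.out = n_deg)
      lfc[idx] <- sgn * planted_lfc
    }
    mu <- outer(mu0, rep(1, n_samp))
    mu[, condition == "B"] <- mu[, condition == "B"] * 2^lfc
    mu <- sweep(mu, 2, library_sizes, "*")
    size <- if (dispersion == 0) Inf else 1 / dispersion
    counts <- matrix(
      rnbinom(n_genes * n_samp, mu = as.vector(mu), size = size),
      n_genes, n_samp, dimnames = list(genes, samples)
    )
    storage.mode(counts) <- "integer"
    gene_lengths <- tibble(
      gene_id = genes,
      length_bp = pmax(200L, as.integer(round(rlnorm(n_genes, log(1500), 0.6))))
    )
    list(
      counts = counts,
      condition = condition,
      gene_lengths = gene_lengths,
      truth = list(
        planted_deg_ids = genes[lfc != 0],
        planted_lfc = setNames(lfc[lfc != 0], genes[lfc != 0]),
        dispersion = dispersion,
        library_sizes = setNames(library_sizes, samples),
        seed = seed
      )
    )
  })
}

#' Simulate a confidence-weighted interactome with planted signaling chains
#'
#' Builds a random background interaction graph plus one high-confidence
#' chain from each source to a target through fresh intermediate nodes. All
#' planted-edge confidences exceed every decoy confidence, and no decoy edge
#' connects a source directly to a target, so each planted chain is the
#' cheapest route from its source under the negative-log-confidence cost.
#'
#' @param n_nodes Total node count (sources, targets, planted intermediates
#'   and background filler).
#' @param n_edges Number of background (decoy) edges.
#' @param sources,targets Disjoint node name vectors.
#' @param path_length Edges per planted chain (>= 2 recommended; shorter
#'   chains are allowed with a warning).
#' @param planted_conf Confidence on planted edges.
#' @param decoy_conf_range Range of decoy confidences, strictly below
#'   `planted_conf`.
#' @param seed Integer seed.
#' @return List with `interactome` (a `pg_interactome`) and `truth`
#'   (planted node paths per source, seed).
#' @export
simulate_interactome <- function(n_nodes = 30,
                                 n_edges = 60,
                                 sources = sprintf("SRC%02d", 1:4),
                                 targets = sprintf("TF%02d", 1:3),
                                 path_length = 3,
                                 planted_conf = 0.99,
                                 decoy_conf_range = c(0.05, 0.6),
                                 seed = 1) {
  if (length(intersect(sources, targets)) > 0) {
    pg_abort("`sources` and `targets` must be disjoint.")
  }
  if (path_length < 2) {
    pg_warn("Planted chains with fewer than 2 edges give trivial paths.")
  }
  if (max(decoy_conf_range) >= planted_conf) {
    pg_abort("Decoy confidences must stay below `planted_conf`.")
  }
  n_inter <- length(sources) * (path_length - 1)
  n_core <- length(sources) + length(targets) + n_inter
  if (n_nodes < n_core) {
    pg_abort(sprintf("`n_nodes` must be at least %d for these chains.", n_core))
  }
  with_seed(seed, {
    inter_nodes <- sprintf("I%03d", seq_len(n_inter))
    filler <- sprintf("N%03d", seq_len(n_nodes - n_core))
    nodes <- c(sources, targets, inter_nodes, filler)

    planted_paths <- vector("list", length(sources))
    names(planted_paths) <- sources
    edge_a <- character(0); edge_b <- character(0); conf <- numeric(0)
    ptr <- 0
    for (i in seq_along(sources)) {
      mids <- inter_nodes[ptr + seq_len(path_length - 1)]
      ptr <- ptr + path_length - 1
      path <- c(sources[i], mids, targets[((i - 1) %% length(targets)) + 1])
      planted_paths[[i]] <- path
      edge_a <- c(edge_a, path[-length(path)])
      edge_b <- c(edge_b, path[-1])
      conf <- c(conf, rep(planted_conf, length(path) - 1))
    }

    # candidate decoy pairs: everything except self-loops, planted pairs and
    # direct source-target shortcuts
    pairs <- t(utils::combn(nodes, 2))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    planted_keys <- key(edge_a, edge_b)
    shortcut <- (pairs[, 1] %in% sources & pairs[, 2] %in% targets) |
      (pairs[, 2] %in% sources & pairs[, 1] %in% targets)
    ok <- !(key(pairs[, 1], pairs[, 2]) %in% planted_keys) & !shortcut
    pairs <- pairs[ok, , drop = FALSE]
    n_bg <- min(n_edges, nrow(pairs))
    if (n_bg > 0) {
      pick <- sample.int(nrow(pairs), n_bg)
      edge_a <- c(edge_a, pairs[pick, 1])
      edge_b <- c(edge_b, pairs[pick, 2])
      conf <- c(conf, runif(n_bg, decoy_conf_range[1], decoy_conf_range[2]))
    }
    net <- as_interactome(tibble(
      node_a = edge_a, node_b = edge_b, confidence = round(conf, 6)
    ))
    list(
      interactome = net,
      truth = list(
        planted_paths = planted_paths,
        planted_conf = planted_conf,
        sources = sources,
        targets = targets,
        seed = seed
      )
    )
  })
}

#' Simulate a transcription-factor regulon collection
#'
#' Decoy TFs draw their targets uniformly from the gene universe; planted
#' TFs draw each target from the supplied DEG set with probability
#' `enrichment_strength` (and uniformly otherwise), planting hypergeometric
#' enrichment of known strength.
#'
#' @param universe Character vector of all testable genes.
#' @param deg_set Genes considered differentially expressed.
#' @param n_tfs Number of TFs.
#' @param targets_per_tf Regulon size (must not exceed the universe).
#' @param planted_tf_ids Names of the enriched TFs; must be a subset of the
#'   generated TF names `TF001 ... TFn`.
#' @param enrichment_strength Probability a planted TF's target is drawn
#'   from `deg_set` (1 = regulon fully inside the DEGs).
#' @param seed Integer seed.
#' @return List with `regulons` (named list, GMT-compatible) and `truth`.
#' @export
simulate_regulons <- function(universe,
                              deg_set,
                              n_tfs = 50,
                              targets_per_tf = 20,
                              planted_tf_ids = sprintf("TF%03d", 1:5),
                              enrichment_strength = 0.8,
                              seed = 1) {
  if (targets_per_tf > length(universe)) {
    pg_abort("`targets_per_tf` exceeds the universe size.")
  }
  deg_set <- intersect(deg_set, universe)
  tf_names <- sprintf("TF%03d", seq_len(n_tfs))
  if (!all(planted_tf_ids %in% tf_names)) {
    pg_abort("`planted_tf_ids` must be a subset of the generated TF names.")
  }
  assert_prob(enrichment_strength, "enrichment_strength")
  non_deg <- setdiff(universe, deg_set)
  with_seed(seed, {
    regulons <- lapply(tf_names, function(tf) {
      if (tf %in% planted_tf_ids && length(deg_set) > 0 &&
          enrichment_strength > 0) {
        # force ~Binomial(k, strength) targets into the DEG set; the rest
        # are uniform over the remaining universe, so strength 0 coincides
        # exactly with the decoy procedure
        n_forced <- min(rbinom(1, targets_per_tf, enrichment_strength),
                        length(deg_set))
        n_forced <- max(n_forced, targets_per_tf - length(non_deg))
        forced <- sample(deg_set, n_forced)
        rest <- sample(setdiff(universe, forced),
                       targets_per_tf - n_forced)
        sort(c(forced, rest))
      } else {
        sort(sample(universe, targets_per_tf))
      }
    })
    names(regulons) <- tf_names
    list(
      regulons = regulons,
      truth = list(
        planted_tf_ids = planted_tf_ids,
        enrichment_strength = enrichment_strength,
        targets_per_tf = targets_per_tf,
        seed = seed
      )
    )
  })
}
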