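# End-to-end orchestration of the three-step pipeline: expression analysis
# and cohort statistics, significant-TF inference, and signaling-network
# reconstruction — on synthetic inputs generated in-run (default) or on
# user-supplied files.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with the published
#' defaults (z cutoff 3.0 / 3 genes, |log2FC| >= 1 and BH padj <= 0.01,
#' interactome confidence >= 0.4 with the UBC hub removed, k1 = 1000,
#' k2 = 50000) and the synthetic-input settings. Override any entry via
#' `...`.
#'
#' @param outdir Output directory for stage outputs and the manifest.
#' @param seed Global integer seed; every stage's randomness derives from
#'   it.
#' @param ... Named overrides of the defaults listed below.
#' @return A `pg_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("pgnet_run_"), seed = 1, ...) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    # synthetic cohort
    n_universe = 600,
    set_sizes = c(PG = 34, EMT = 40, INV = 30, CSC = 25),
    n_tumor = 510,
    n_normal = 58,
    pg_pos_frac = 0.48,
    hazard_ratio = 2,
    baseline_hazard = 0.02,
    censor_rate = 0.3,
    # scoring / stratification
    cutoff = 3.0,
    min_genes = 3,
    # synthetic counts
    n_genes = 4000,
    n_per_group = c(3, 3),
    planted_frac = 0.05,
    planted_lfc = 2,
    dispersion = 0.05,
    # differential expression
    min_total = 10,
    lfc_thresh = 1.0,
    padj_thresh = 0.01,
    # regulons / TF inference
    n_tfs = 40,
    targets_per_tf = 20,
    planted_tf_ids = sprintf("TF%03d", 1:4),
    enrichment_strength = 0.8,
    tf_padj_thresh = 0.05,
    tf_min_overlap = 3,
    # interactome / reconstruction
    n_nodes = 26,
    n_edges = 40,
    network_sources = sprintf("SRC%02d", 1:4),
    min_conf = 0.4,
    drop_nodes = "UBC",
    k1 = 200,
    k2 = 2000,
    # pathway ORA over network intermediates
    n_pathways = 10,
    pathway_size = 8
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    pg_abort(sprintf("Unknown configuration field(s): %s",
                     paste(bad, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over)
  class(cfg) <- "pg_config"
  cfg
}

run_stage <- function(name, manifest_env, code) {
  pg_log("== stage: %s ==", name)
  res <- tryCatch(force(code), error = function(e) {
    pg_abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
             class = "pgnet_stage_error")
  })
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

#' Run the full pipeline
#'
#' Executes simulate -> score/stratify -> cohort statistics -> differential
#' expression -> TF inference -> two-stage network reconstruction ->
#' pathway over-representation, writing every stage output as TSV/GMT/JSON
#' under `config$outdir` plus a `manifest.json` recording the package
#' version, seed, parameters and per-stage row counts. A rerun with the
#' same configuration and seed reproduces all outputs byte-identically.
#'
#' @param config A `pg_config` from [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pg_config")) {
    pg_abort("`config` must come from pipeline_config().")
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  env <- new.env(parent = emptyenv())
  env$stages <- character(0)
  counts_of <- list()

  # -- stage 1: synthetic inputs ---------------------------------------------
  sim <- run_stage("simulate", env, {
    gene_sets <- synthetic_gene_sets(config$n_universe, config$set_sizes,
                                     seed = config$seed)
    cohort <- simulate_cohort(
      gene_sets,
      n_tumor = config$n_tumor, n_normal = config$n_normal,
      pg_pos_frac = config$pg_pos_frac,
      hazard_ratio = config$hazard_ratio,
      baseline_hazard = config$baseline_hazard,
      censor_rate = config$censor_rate,
      seed = config$seed
    )
    cnt <- simulate_counts(
      n_genes = config$n_genes, n_per_group = config$n_per_group,
      planted_frac = config$planted_frac, planted_lfc = config$planted_lfc,
      dispersion = config$dispersion, seed = config$seed + 1L
    )
    reg <- simulate_regulons(
      universe = rownames(cnt$counts),
      deg_set = cnt$truth$planted_deg_ids,
      n_tfs = config$n_tfs, targets_per_tf = config$targets_per_tf,
      planted_tf_ids = config$planted_tf_ids,
      enrichment_strength = config$enrichment_strength,
      seed = config$seed + 2L
    )
    net <- simulate_interactome(
      n_nodes = config$n_nodes, n_edges = config$n_edges,
      sources = config$network_sources,
      targets = config$planted_tf_ids,
      seed = config$seed + 3L
    )
    expr_tbl <- as_tibble(cohort$expression, rownames = "gene_id")
    write_stage_tsv(expr_tbl, pth("expression.tsv"))
    write_stage_tsv(cohort$clinical, pth("clinical.tsv"))
    write_stage_tsv(as_tibble(cnt$counts, rownames = "gene_id"),
                    pth("counts.tsv"))
    write_stage_tsv(cnt$gene_lengths, pth("gene_lengths.tsv"))
    write_gmt(gene_sets, pth("gene_sets.gmt"))
    write_gmt(reg$regulons, pth("regulons.gmt"))
    write_interactome(net$interactome, pth("interactome.tsv"))
    jsonlite::write_json(
      list(
        cohort_seed = cohort$truth$seed,
        planted_pos_frac = config$pg_pos_frac,
        planted_deg_ids = cnt$truth$planted_deg_ids,
        planted_tf_ids = reg$truth$planted_tf_ids,
        planted_paths = net$truth$planted_paths
      ),
      pth("truth.json"), auto_unbox = TRUE, pretty = TRUE
    )
    list(gene_sets = gene_sets, cohort = cohort, counts = cnt,
         regulons = reg, interactome = net)
  })
  counts_of$simulate <- c(
    genes_cohort = nrow(sim$cohort$expression),
    genes_counts = nrow(sim$counts$counts),
    interactome_edges = nrow(sim$interactome$interactome)
  )

  # -- stage 2: scoring and stratification -----------------------------------
  scored <- run_stage("score", env, {
    z <- compute_zscores(sim$cohort$expression, sim$cohort$normal_ids)
    sc <- score_cohort(z, sim$gene_sets, pg_set = "PG",
                       cutoff = config$cutoff, min_genes = config$min_genes)
    write_stage_tsv(as_tibble(sc), pth("scores.tsv"))
    jsonlite::write_json(as.list(glance(sc)), pth("stratification.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(z = z, scores = sc)
  })
  counts_of$score <- c(samples_labeled = nrow(scored$scores))

  # -- stage 3: cohort statistics --------------------------------------------
  stats_res <- run_stage("stats", env, {
    sc <- scored$scores
    two <- dplyr::filter(sc, .data$pg_label %in% c("PG+", "PG-"))
    wil <- wilcoxon_rank_sum(two$PG[two$pg_label == "PG+"],
                             two$PG[two$pg_label == "PG-"])
    spearmans <- lapply(setdiff(names(config$set_sizes), "PG"), function(s) {
      mutate(spearman_rho(sc$PG, sc[[s]]), comparison = paste0("PG_vs_", s))
    })
    clin <- left_join(sim$cohort$clinical,
                      sc[, c("sample_id", "pg_label")], by = "sample_id")
    surv2 <- dplyr::filter(clin, .data$pg_label %in% c("PG+", "PG-"))
    km <- km_curve(surv2)
    lr <- logrank_test(surv2)
    tests <- bind_rows(
      mutate(tidy(wil), comparison = "PGscore_pos_vs_neg"),
      bind_rows(lapply(spearmans, tidy)),
      mutate(tidy(lr), comparison = "survival_pos_vs_neg")
    )
    write_stage_tsv(tidy(km), pth("km_curves.tsv"))
    jsonlite::write_json(tests, pth("stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(tests = tests, km = km)
  })
  counts_of$stats <- c(tests = nrow(stats_res$tests))

  # -- stage 4: differential expression --------------------------------------
  de <- run_stage("de", env, {
    kept <- prefilter_genes(sim$counts$counts, min_total = config$min_total)
    sf <- size_factors(kept)
    res <- nb_wald_test(kept, sim$counts$condition, sf = sf)
    res <- call_degs(res, lfc_thresh = config$lfc_thresh,
                     padj_thresh = config$padj_thresh)
    tpm_mat <- tpm(kept, sim$counts$gene_lengths)
    write_stage_tsv(as_tibble(res), pth("de_results.tsv"))
    write_stage_tsv(as_tibble(tpm_mat, rownames = "gene_id"), pth("tpm.tsv"))
    jsonlite::write_json(as.list(glance(res)), pth("de_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(result = res, size_factors = sf)
  })
  counts_of$de <- c(genes_tested = nrow(de$result),
                    degs = length(deg_ids(de$result)))

  # -- stage 5: transcription-factor inference -------------------------------
  tfs <- run_stage("tfs", env, {
    enr <- infer_significant_tfs(
      deg_set = deg_ids(de$result),
      regulons = sim$regulons$regulons,
      universe = de$result$gene_id,
      padj_thresh = config$tf_padj_thresh,
      min_overlap = config$tf_min_overlap
    )
    flat <- mutate(as_tibble(enr),
                   genes = vapply(.data$genes, paste, character(1),
                                  collapse = ";"))
    write_stage_tsv(flat, pth("tf_enrichment.tsv"))
    enr
  })
  counts_of$tfs <- c(significant_tfs = length(significant_tfs(tfs)))

  # -- stage 6: two-stage network reconstruction -----------------------------
  network <- run_stage("network", env, {
    filtered <- filter_interactome(sim$interactome$interactome,
                                   min_conf = config$min_conf,
                                   drop_nodes = config$drop_nodes)
    targets <- significant_tfs(tfs)
    if (length(intersect(targets,
                         unique(c(filtered$node_a, filtered$node_b)))) == 0) {
      pg_abort("No significant TF is present in the interactome.")
    }
    ts <- two_stage_reconstruction(
      filtered, sources = config$network_sources, targets = targets,
      k1 = config$k1, k2 = config$k2
    )
    for (stage in c("stage1", "final")) {
      nw <- ts[[stage]]
      write_stage_tsv(
        mutate(nw$paths,
               path = vapply(.data$path, paste, character(1), collapse = "|")),
        pth(sprintf("%s_paths.tsv", stage))
      )
      write_stage_tsv(nw$edges, pth(sprintf("%s_edges.tsv", stage)))
      write_stage_tsv(nw$nodes, pth(sprintf("%s_nodes.tsv", stage)))
    }
    ts
  })
  counts_of$network <- c(
    stage1_paths = nrow(network$stage1$paths),
    final_nodes = nrow(network$final$nodes),
    final_edges = nrow(network$final$edges)
  )

  # -- stage 7: pathway over-representation of network intermediates ---------
  enrich <- run_stage("enrich", env, {
    node_universe <- unique(c(sim$interactome$interactome$node_a,
                              sim$interactome$interactome$node_b))
    planted_mid <- unique(unlist(lapply(
      sim$interactome$truth$planted_paths,
      function(p) p[-c(1, length(p))]
    )))
    pathways <- with_seed(config$seed + 4L, {
      ps <- lapply(seq_len(config$n_pathways), function(i) {
        sort(sample(node_universe, min(config$pathway_size,
                                       length(node_universe))))
      })
      names(ps) <- sprintf("PATHWAY%02d", seq_along(ps))
      ps$PATHWAY_PLANTED <- sort(unique(c(
        planted_mid,
        sample(node_universe, max(0, config$pathway_size - length(planted_mid)))
      )))
      ps
    })
    intermediates <- network$final$nodes$node[
      network$final$nodes$role == "intermediate"
    ]
    ora <- hypergeom_overrep(intermediates, pathways, node_universe)
    flat <- mutate(as_tibble(ora),
                   genes = vapply(.data$genes, paste, character(1),
                                  collapse = ";"))
    write_stage_tsv(flat, pth("pathway_enrichment.tsv"))
    ora
  })
  counts_of$enrich <- c(pathways_tested = nrow(enrich))

  manifest <- list(
    package = "pgnet",
    version = as.character(utils::packageVersion("pgnet")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    stages = env$stages,
    row_counts = counts_of
  )
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pg_log("Pipeline complete: %d stages, outputs in %s",
         length(env$stages), outdir)
  invisible(list(
    sim = sim, scores = scored$scores, stats = stats_res, de = de$result,
    tfs = tfs, network = network, pathways = enrich, manifest = manifest,
    outdir = outdir
  ))
}
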