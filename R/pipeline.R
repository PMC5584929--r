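## End-to-end orchestration: simulate (or load) -> quantify -> normalise ->
## classify -> co-expression -> ordination -> BEST, with every intermediate
## persisted as TSV and a run report assembled at the end.

#' Pipeline configuration
#'
#' All stage parameters in one validated, serialisable list. Every random
#' stage derives its seed from the single top-level `seed`, which is
#' mandatory: a configuration without a seed fails validation before any
#' stage runs.
#'
#' @param seed integer seed (required).
#' @param sim named list of [sim_config()] overrides (synthetic input).
#' @param counts_path,env_path,models_path optional paths to a precomputed
#'   gene-by-sample count TSV, environmental TSV and gene models (GFF3/BED);
#'   when `counts_path` is set the simulate stage is skipped.
#' @param sam_paths optional named vector of per-sample SAM files to
#'   quantify instead of simulating counts directly.
#' @param filters quantification filter settings.
#' @param rpoB_gene host rpoB gene name.
#' @param min_total_pairs negligible-sample exclusion threshold.
#' @param markers a [marker_set()].
#' @param tie_band indeterminate band half-width for the state call.
#' @param coexpr co-expression settings (`alpha`, `edge_p`, `n_perm`, `k`,
#'   `linkage`).
#' @param ordination nMDS settings (`n_restarts`, `max_iter`, `tol`).
#' @param best BEST settings (`max_subset_size`, `n_perm`).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = list(),
                            counts_path = NULL, env_path = NULL,
                            models_path = NULL, sam_paths = NULL,
                            filters = list(min_length_fraction = 0.9,
                                           min_identity_fraction = 0.9,
                                           tie_policy = "random_best",
                                           containment = "both_within"),
                            rpoB_gene = "rpoB",
                            min_total_pairs = 10,
                            markers = marker_set(),
                            tie_band = 0,
                            coexpr = list(alpha = 0.05, edge_p = 0.1,
                                          n_perm = 999, k = 3,
                                          linkage = "average"),
                            ordination = list(n_restarts = 50,
                                              max_iter = 300, tol = 1e-7),
                            best = list(max_subset_size = 5, n_perm = 99)) {
  if (missing(seed) || is.null(seed))
    stop_config("pipeline_config requires an explicit seed")
  cfg <- list(seed = seed, sim = sim, counts_path = counts_path,
              env_path = env_path, models_path = models_path,
              sam_paths = sam_paths, filters = filters,
              rpoB_gene = rpoB_gene, min_total_pairs = min_total_pairs,
              markers = unclass(markers), tie_band = tie_band,
              coexpr = coexpr, ordination = ordination, best = best)
  with_seed(cfg$seed, NULL)               # validates the seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips through serialisation unchanged.
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  args$markers <- NULL
  cfg <- do.call(pipeline_config, args)
  if (!is.null(raw$markers))
    cfg$markers <- raw$markers
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes quantify (or simulate) -> normalise -> classify -> co-expression
#' -> ordination -> BEST in order, persisting every intermediate as TSV
#' under `out_dir`, and assembles a run report. Deterministic given the
#' configuration: re-running with an identical config reproduces the report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for intermediates (created).
#' @return a `run_report` list: sample exclusions, state calls and summary,
#'   marker correlations, cluster report, collapsed groups, ordination,
#'   environmental fit and BEST result, plus per-stage provenance.
#' @export
run_pipeline <- function(config, out_dir = tempfile("phagestate_run")) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  markers <- do.call(marker_set, config$markers)
  truth <- NULL

  ## --- input stage -------------------------------------------------------
  if (!is.null(config$counts_path)) {
    stage_log("input", "reading counts from ", config$counts_path)
    counts <- read_counts(config$counts_path)
    if (is.null(config$models_path))
      stop_config("models_path is required with counts_path")
    models <- read_gene_models(config$models_path)
    env <- read_env_table(config$env_path)
    metadata <- NULL
  } else if (!is.null(config$sam_paths)) {
    stage_log("quantify", length(config$sam_paths), " SAM file(s)")
    if (is.null(config$models_path))
      stop_config("models_path is required with sam_paths")
    models <- read_gene_models(config$models_path)
    counts <- do.call(quantify_sam,
                      c(list(sam_paths = config$sam_paths, models = models,
                             seed = config$seed), config$filters))
    env <- read_env_table(config$env_path)
    metadata <- NULL
  } else {
    stage_log("simulate", "synthetic dataset (seed ", config$seed, ")")
    sim_cfg <- do.call(sim_config, utils::modifyList(
      list(seed = config$seed), config$sim))
    ds <- simulate_dataset(sim_cfg)
    counts <- ds$counts; models <- ds$models
    env <- ds$truth$env_table
    metadata <- ds$truth$metadata
    truth <- ds$truth
    write_sim_truth(ds$truth, out_dir)
  }
  write_counts(counts, file.path(out_dir, "counts.tsv"))

  ## --- exclusion stage ---------------------------------------------------
  flags <- flag_negligible(counts, models, rpoB_gene = config$rpoB_gene,
                           min_total_pairs = config$min_total_pairs)
  excluded <- flags$sample[flags$excluded]
  stage_log("exclude", length(excluded), " sample(s) negligible")
  if (length(excluded)) {
    counts <- drop_samples(counts, excluded)
    env <- env[setdiff(rownames(env), excluded), , drop = FALSE]
  }
  utils::write.table(flags, file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- normalise ---------------------------------------------------------
  stage_log("normalize", "library-size, rpoB and log2(x+10) paths")
  expr_lib <- libsize_normalize(counts)
  expr_rpob <- rpob_normalize(counts, rpoB_gene = config$rpoB_gene)
  expr_log <- log2_shift(counts)
  write_expression(expr_lib, file.path(out_dir, "expr_libsize.tsv"))
  write_expression(expr_rpob, file.path(out_dir, "expr_rpob.tsv"))

  ## --- classify ----------------------------------------------------------
  calls <- classify_state(expr_rpob, markers, tie_band = config$tie_band)
  corr <- marker_correlations(expr_log, markers)
  write_state_calls(calls, file.path(out_dir, "state_calls.tsv"))
  utils::write.table(corr, file.path(out_dir, "marker_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("classify", sum(calls$state == "lytic"), " lytic / ",
            sum(calls$state == "lysogenic"), " lysogenic / ",
            sum(calls$state == "indeterminate"), " indeterminate")

  ## --- co-expression (phage genome only) ---------------------------------
  phage_genes <- models$gene_id[models$genome_id == "phage"]
  expr_coex <- log2_shift(expression_matrix(
    expr_lib$values[intersect(phage_genes, rownames(expr_lib$values)), ,
                    drop = FALSE]))
  assoc <- gene_association(expr_coex)
  tree <- cluster_genes(assoc, linkage = config$coexpr$linkage)
  collapsed <- collapse_indistinguishable(tree, expr_coex,
                                          alpha = config$coexpr$alpha,
                                          n_perm = config$coexpr$n_perm,
                                          seed = config$seed)
  clusters <- summarize_clusters(tree, assoc, markers, k = config$coexpr$k,
                                 edge_p = config$coexpr$edge_p)
  write_dendrogram_newick(tree, file.path(out_dir, "coexpression.nwk"))
  utils::write.table(collapsed, file.path(out_dir, "collapsed_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clusters$summary, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("coexpr", nrow(clusters$summary), " major clusters; ",
            sum(collapsed$collapsed), " genes in collapsed branches")

  ## --- ordination + environmental drivers --------------------------------
  expr_ord <- sqrt_transform(expression_matrix(
    expr_lib$values[intersect(phage_genes, rownames(expr_lib$values)), ,
                    drop = FALSE]))
  d <- bray_curtis(expr_ord)
  ord <- nmds(d, n_restarts = config$ordination$n_restarts,
              max_iter = config$ordination$max_iter,
              tol = config$ordination$tol, seed = config$seed)
  fit <- env_fit(ord, env, n_perm = config$best$n_perm, seed = config$seed)
  best <- best_bioenv(d, env, max_subset_size = config$best$max_subset_size,
                      n_perm = config$best$n_perm, seed = config$seed)
  utils::write.table(
    data.frame(sample = rownames(ord$points), ord$points),
    file.path(out_dir, "ordination.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit, file.path(out_dir, "envfit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(best$per_size, file.path(out_dir, "best.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("ordinate", "stress-1 = ", signif(ord$stress, 4),
            "; BEST rho = ", signif(best$rho, 4))

  ## --- report ------------------------------------------------------------
  grouped <- if (!is.null(metadata))
    summarize_by_group(calls, metadata, seed = config$seed) else NULL
  report <- structure(list(
    config = config,
    exclusions = flags,
    state_calls = calls,
    state_summary = table(calls$state),
    marker_correlations = corr,
    cluster_report = clusters,
    collapsed_groups = collapsed,
    ordination = ord,
    env_fit = fit,
    best = best,
    grouped_summary = grouped,
    truth = truth,
    out_dir = out_dir
  ), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("phagestate run report\n")
  cat("  samples retained:", nrow(x$state_calls), "\n")
  print(x$state_summary)
  cat("  nMDS stress-1:", signif(x$ordination$stress, 4), "\n")
  cat("  BEST subset: {", paste(x$best$best_subset, collapse = ", "),
      "} rho =", signif(x$best$rho, 4), "\n")
  invisible(x)
}

#' Cross-tabulate state calls by station and month
#'
#' Chi-square independence test of state against station; the p-value is
#' simulated (seeded) whenever any expected cell is below 5.
#'
#' @param calls a `state_calls` data frame.
#' @param metadata data frame with `sample`, `station`, `month`.
#' @param seed RNG seed for the simulated p-value.
#' @param B simulation replicates.
#' @return list with `by_station`, `by_month` tables and `station_test`
#'   (statistic, p_value, simulated flag).
#' @export
summarize_by_group <- function(calls, metadata, seed = 1, B = 2000) {
  missing_ids <- setdiff(calls$sample, metadata$sample)
  if (length(missing_ids))
    stop_data("sample id(s) missing from metadata: ",
              paste(missing_ids, collapse = ", "))
  m <- metadata[match(calls$sample, metadata$sample), ]
  by_station <- table(station = m$station, state = calls$state)
  by_month <- table(month = m$month, state = calls$state)
  tab <- by_station[rowSums(by_station) > 0, colSums(by_station) > 0,
                    drop = FALSE]
  test <- NULL
  if (all(dim(tab) >= 2L)) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    simulate <- any(expected < 5)
    ch <- with_seed(seed, suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = simulate, B = B)))
    test <- list(statistic = unname(ch$statistic),
                 p_value = ch$p.value, simulated = simulate)
  }
  list(by_station = by_station, by_month = by_month, station_test = test)
}

#' Read an environmental table from TSV
#'
#' First column is the sample id; remaining columns are numeric variables.
#'
#' @param path TSV path.
#' @return data frame with samples as rownames.
#' @export
read_env_table <- function(path) {
  if (is.null(path)) stop_config("an environmental table path is required")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  df
}
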