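## Synthetic-data generator: genome models, environmental tables with latent
## lytic/lysogenic states, negative-binomial counts, and paired-end SAM
## fixtures, all with recorded ground truth.

#' Generate phage and host gene models
#'
#' Lays out one phage genome of `n_phage_genes` non-overlapping ORFs (the
#' marker genes gp091, gp135 and gp136 are always present, renamed onto the
#' last ORFs when the genome is too short to contain their natural indices)
#' and one host genome containing `rpoB`. Every gene carries its
#' co-expression block label (`lysogeny`, `packaging_lysis`,
#' `replication_structural` or `host`); non-anchor phage genes are assigned
#' to blocks at the default 12/60/112 proportions of the 184-gene genome.
#'
#' @param config a [sim_config()].
#' @return a [gene_model_set()] with a `block` column.
#' @export
make_genome_models <- function(config) {
  validate_sim_config(config)
  n <- config$n_phage_genes
  with_seed(config$seed, {
    gene_names <- sprintf("gp%03d", seq_len(n))
    anchors <- c(LYSOGENY_ANCHORS, PACKAGING_ANCHORS, REPLICATION_ANCHORS)
    required <- if (n >= 20) anchors else CORE_MARKERS
    missing <- setdiff(required, gene_names)
    if (length(missing)) {
      replaceable <- rev(setdiff(gene_names, required))
      if (length(missing) > length(replaceable))
        stop_config("n_phage_genes too small to place all named marker genes")
      gene_names[match(replaceable[seq_along(missing)], gene_names)] <- missing
    }

    ## block assignment: anchors fixed, the rest fill the 12/60/112 quota
    block <- rep(NA_character_, n)
    block[gene_names %in% LYSOGENY_ANCHORS] <- "lysogeny"
    block[gene_names %in% PACKAGING_ANCHORS] <- "packaging_lysis"
    block[gene_names %in% REPLICATION_ANCHORS] <- "replication_structural"
    target <- round(n * c(lysogeny = 12, packaging_lysis = 60,
                          replication_structural = 112) / 184)
    quota <- pmax(target - table(factor(block, names(target))), 0)
    free <- which(is.na(block))
    fill <- rep(names(quota), quota)
    if (length(fill) < length(free))
      fill <- c(fill, rep("replication_structural", length(free) - length(fill)))
    block[free] <- sample(fill)[seq_along(free)]

    ## ORF layout: lengths 300-1500 bp, gaps 20-200 bp
    lay <- function(k) {
      len <- floor(stats::runif(k, 300, 1501))
      gap <- floor(stats::runif(k, 20, 201))
      start <- cumsum(c(100, len[-k] + gap[-k]))
      list(start = start, end = start + len)
    }
    ph <- lay(n)
    nh <- config$n_host_genes
    ho <- lay(nh)
    host_names <- sprintf("host%03d", seq_len(nh))
    host_names[min(2L, nh)] <- "rpoB"

    gene_model_set(
      genome_id = c(rep("phage", n), rep("host", nh)),
      gene_id = c(gene_names, host_names),
      start = c(ph$start, ho$start),
      end = c(ph$end, ho$end),
      strand = "+",
      block = c(block, rep("host", nh))
    )
  })
}

#' Simulate environmental covariates and latent infection states
#'
#' Environmental variables are drawn from a correlated multivariate normal
#' (exchangeable correlation `env_correlation`) and rescaled to realistic
#' limnological units; the latent per-sample state is Bernoulli with
#' P(lysogenic) = logistic(intercept + coefficients . standardized env).
#'
#' @param config a [sim_config()].
#' @param models a [gene_model_set()] from [make_genome_models()] (supplies
#'   the per-gene block labels recorded in the truth object).
#' @return a `sim_truth` list with `state_per_sample`, `block_of_gene`,
#'   `env_table`, `env_z` (the standardized draws), `metadata` (station and
#'   month per sample) and a slot for `expected_mean_matrix`.
#' @export
simulate_env_and_states <- function(config, models) {
  validate_sim_config(config)
  vars <- env_variable_names()
  p <- length(vars)
  coef_full <- stats::setNames(numeric(p), vars)
  coef_full[names(config$env_state_coefficients)] <- config$env_state_coefficients
  n <- config$n_samples
  with_seed(config$seed + 1L, {
    sigma <- matrix(config$env_correlation, p, p)
    diag(sigma) <- 1
    z <- matrix(MASS::mvrnorm(n, mu = numeric(p), Sigma = sigma),
                nrow = n, dimnames = list(NULL, vars))
    env <- matrix(vapply(vars, function(v)
      ENV_SCALES[[v]][1] + ENV_SCALES[[v]][2] * z[, v], numeric(n)),
      nrow = n, dimnames = list(NULL, vars))
    eta <- config$env_intercept + drop(z %*% coef_full)
    state <- ifelse(stats::runif(n) < stats::plogis(eta), "lysogenic", "lytic")

    station <- paste0("T", sprintf("%02d", ((seq_len(n) - 1L) %% 7L) + 1L))
    month <- 6L + ((seq_len(n) - 1L) %/% 7L) %% 5L
    sample_id <- make.unique(paste0(station, "_", month), sep = "b")
    env <- as.data.frame(env)
    rownames(env) <- sample_id

    structure(
      list(
        state_per_sample = stats::setNames(state, sample_id),
        block_of_gene = stats::setNames(models$block, models$gene_id),
        env_table = env,
        env_z = z,
        p_lysogenic = stats::setNames(stats::plogis(eta), sample_id),
        metadata = data.frame(sample = sample_id, station = station,
                              month = month, stringsAsFactors = FALSE),
        expected_mean_matrix = NULL
      ),
      class = "sim_truth"
    )
  })
}

## per-gene x per-sample fold factor implied by block and state
state_fold_matrix <- function(block_of_gene, state_per_sample, fold) {
  up_lysogenic <- block_of_gene == "lysogeny"
  up_lytic <- block_of_gene %in% c("packaging_lysis", "replication_structural")
  f <- matrix(1, length(block_of_gene), length(state_per_sample),
              dimnames = list(names(block_of_gene), names(state_per_sample)))
  f[up_lysogenic, state_per_sample == "lysogenic"] <- fold
  f[up_lytic, state_per_sample == "lytic"] <- fold
  f
}

#' Simulate the gene-by-sample count matrix
#'
#' Counts are negative binomial with mean
#' `libsize(s) * baseline(g) * foldfactor(block(g), state(s))` and fixed
#' dispersion. Baselines are log-normal (reduced spread for the marker
#' genes, and a 10x boost for `rpoB` so host normalisation is stable) and
#' normalized to sum to one at fold 1. The expectation matrix is attached to
#' the result as attribute `expected_mean` and, via [simulate_dataset()],
#' recorded in the truth object.
#'
#' @param truth a `sim_truth` from [simulate_env_and_states()].
#' @param models the matching [gene_model_set()].
#' @param config the [sim_config()].
#' @param draw_seed seed for the negative-binomial draw itself (defaults to
#'   `config$seed + 4`); varying it replicates count noise over a fixed
#'   expectation matrix, which is what a resampling check of the count model
#'   needs.
#' @return a [count_matrix()] with attribute `expected_mean`.
#' @export
simulate_counts <- function(truth, models, config,
                            draw_seed = config$seed + 4L) {
  validate_sim_config(config)
  if (!identical(sort(models$gene_id), sort(names(truth$block_of_gene))))
    stop_data("truth and models disagree on the gene set")
  if (config$dispersion <= 0) stop_config("dispersion must be > 0")
  genes <- models$gene_id
  n <- config$n_samples
  with_seed(config$seed + 2L, {
    sdlog <- ifelse(genes %in% CORE_MARKERS, config$marker_sdlog,
                    config$baseline_sdlog)
    baseline <- stats::rlnorm(length(genes), config$baseline_meanlog, sdlog)
    baseline[genes == "rpoB"] <- baseline[genes == "rpoB"] * 10
    baseline <- stats::setNames(baseline / sum(baseline), genes)

    libsize <- stats::runif(n, config$library_size_range[1],
                            config$library_size_range[2])
    fold <- state_fold_matrix(truth$block_of_gene[genes],
                              truth$state_per_sample,
                              config$state_fold_change)
    mu <- baseline * fold %*% diag(libsize, n)
    dimnames(mu) <- list(genes, names(truth$state_per_sample))
    counts <- with_seed(draw_seed, matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu)
    ))
    out <- count_matrix(counts,
                        provenance = list(simulated = TRUE, seed = config$seed))
    attr(out, "expected_mean") <- mu
    out
  })
}

#' Simulate a complete ground-truth dataset
#'
#' Convenience wrapper chaining [make_genome_models()],
#' [simulate_env_and_states()] and [simulate_counts()]; the expectation
#' matrix is copied into the truth object.
#'
#' @param config a [sim_config()].
#' @return list with `models`, `truth` and `counts`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  models <- make_genome_models(config)
  truth <- simulate_env_and_states(config, models)
  counts <- simulate_counts(truth, models, config)
  truth$expected_mean_matrix <- attr(counts, "expected_mean")
  list(models = models, truth = truth, counts = counts)
}

#' Write the environmental table / truth tables as TSV
#'
#' @param truth a `sim_truth`.
#' @param dir destination directory.
#' @return invisibly, the paths written.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env_path <- file.path(dir, "env.tsv")
  utils::write.table(
    data.frame(sample = rownames(truth$env_table), truth$env_table,
               check.names = FALSE),
    env_path, sep = "\t", quote = FALSE, row.names = FALSE)
  st_path <- file.path(dir, "states.tsv")
  utils::write.table(
    data.frame(sample = names(truth$state_per_sample),
               state = truth$state_per_sample,
               truth$metadata[, c("station", "month")]),
    st_path, sep = "\t", quote = FALSE, row.names = FALSE)
  bl_path <- file.path(dir, "blocks.tsv")
  utils::write.table(
    data.frame(gene_id = names(truth$block_of_gene),
               block = truth$block_of_gene),
    bl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(env_path, st_path, bl_path))
}
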