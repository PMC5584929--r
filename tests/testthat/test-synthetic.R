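test_that("default genome layout has 184 phage genes, markers and disjoint ORFs", {
  models <- make_genome_models(sim_config())
  phage <- models[models$genome_id == "phage", ]
  host <- models[models$genome_id == "host", ]
  expect_equal(nrow(phage), 184)
  expect_gte(nrow(host), 1)
  expect_true(all(c("gp091", "gp135", "gp136", "rpoB") %in% models$gene_id))
  for (sub in list(phage, host)) {
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start < sub$end))
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  ## anchor genes sit in their documented co-expression blocks
  blk <- stats::setNames(models$block, models$gene_id)
  expect_true(all(blk[c("gp135", "gp136", "gp031", "gp032", "gp171", "gp067")]
                  == "lysogeny"))
  expect_true(all(blk[c("gp069", "gp095", "gp118", "gp134", "gp128")]
                  == "packaging_lysis"))
  expect_true(all(blk[c("gp091", "gp086", "gp087", "gp088", "gp092")]
                  == "replication_structural"))
  expect_identical(unname(blk["rpoB"]), "host")
})

test_that("a minimal 10-gene genome still carries the marker genes", {
  models <- make_genome_models(small_sim_config(n_phage_genes = 10))
  expect_equal(sum(models$genome_id == "phage"), 10)
  expect_true(all(c("gp091", "gp135", "gp136") %in% models$gene_id))
  expect_error(sim_config(n_phage_genes = 5), class = "phagestate_config_error")
})

test_that("generation is a pure function of config and seed", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.data.frame(a$models), as.data.frame(b$models))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$env_table, b$truth$env_table)
  expect_identical(a$truth$state_per_sample, b$truth$state_per_sample)
  c <- simulate_dataset(small_sim_config(seed = 12))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("a symmetric logistic link gives a balanced state mix", {
  cfg <- small_sim_config(n_samples = 2000, env_state_coefficients = numeric(0),
                          env_intercept = 0, seed = 5)
  models <- make_genome_models(cfg)
  truth <- simulate_env_and_states(cfg, models)
  frac <- mean(truth$state_per_sample == "lysogenic")
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("P(lysogenic) is monotone in a strongly weighted variable", {
  cfg <- small_sim_config(n_samples = 50, env_state_coefficients = c(pH = 5),
                          seed = 3)
  truth <- simulate_env_and_states(cfg, make_genome_models(cfg))
  ord <- order(truth$env_table$pH)
  expect_true(all(diff(truth$p_lysogenic[ord]) >= 0))
})

test_that("a saturated negative intercept forces every sample lytic", {
  cfg <- small_sim_config(n_samples = 40, env_state_coefficients = numeric(0),
                          env_intercept = -20, seed = 2)
  truth <- simulate_env_and_states(cfg, make_genome_models(cfg))
  expect_true(all(truth$state_per_sample == "lytic"))
})

test_that("Monte-Carlo count means match the stored expectation matrix", {
  cfg <- small_sim_config(n_samples = 4, n_phage_genes = 12, n_host_genes = 2,
                          library_size_range = c(3000, 5000), seed = 9)
  models <- make_genome_models(cfg)
  truth <- simulate_env_and_states(cfg, models)
  n_rep <- 500
  acc <- 0
  acc2 <- 0
  mu <- NULL
  for (r in seq_len(n_rep)) {
    cm <- simulate_counts(truth, models, cfg, draw_seed = 10000 + r)
    if (is.null(mu)) mu <- attr(cm, "expected_mean")
    acc <- acc + cm$counts
    acc2 <- acc2 + cm$counts^2
  }
  mc_mean <- acc / n_rep
  mc_var <- acc2 / n_rep - mc_mean^2
  se <- sqrt(mc_var / n_rep)
  within <- abs(mc_mean - mu) <= 3 * se
  ## ~99.7% of entries should sit inside a 3-SE band
  expect_gte(mean(within), 0.97)
  ## overdispersion: empirical variance exceeds the mean
  expect_gt(mean(mc_var > mc_mean), 0.95)
})

test_that("fold change 1 removes the state effect on block means", {
  rejections <- 0L
  n_seed <- 30L
  for (s in seq_len(n_seed)) {
    cfg <- small_sim_config(n_samples = 16, state_fold_change = 1, seed = 100 + s)
    ds <- simulate_dataset(cfg)
    st <- ds$truth$state_per_sample
    if (length(unique(st)) < 2L) next
    lys_genes <- names(ds$truth$block_of_gene)[ds$truth$block_of_gene == "lysogeny"]
    norm <- t(ds$counts$counts[lys_genes, , drop = FALSE]) /
      ds$counts$library_size
    per_sample <- log2(rowMeans(norm) + 1e-8)
    p <- stats::t.test(per_sample[st == "lytic"],
                       per_sample[st == "lysogenic"])$p.value
    if (p <= 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)
})

test_that("doubling the library-size range doubles expected totals", {
  cfg1 <- small_sim_config(seed = 21)
  cfg2 <- small_sim_config(seed = 21,
                           library_size_range = 2 * cfg1$library_size_range)
  ds1 <- simulate_dataset(cfg1)
  ds2 <- simulate_dataset(cfg2)
  expect_equal(ds2$truth$expected_mean_matrix,
               2 * ds1$truth$expected_mean_matrix)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(dispersion = 0), class = "phagestate_config_error")
  expect_error(sim_config(state_fold_change = 0.5),
               class = "phagestate_config_error")
  expect_error(sim_config(seq_error_rate = 0.2),
               class = "phagestate_config_error")
  expect_error(sim_config(env_state_coefficients = c(pH = Inf)),
               class = "phagestate_config_error")
  expect_error(sim_config(env_state_coefficients = c(nope = 1)),
               class = "phagestate_config_error")
})

test_that("decoy emission hits the requested fraction and SAM stays parseable", {
  cfg <- small_sim_config(n_samples = 2, library_size_range = c(400, 600),
                          decoy_fraction = 0.2, seed = 31)
  ds <- simulate_dataset(cfg)
  fx <- emit_read_fixtures(ds$counts, ds$models, cfg, tempfile("sam"))
  n_true <- sum(fx$true_pairs)
  n_decoy <- sum(fx$decoy_pairs)
  frac <- n_decoy / (n_true + n_decoy)
  tol <- 4 * sqrt(0.2 * 0.8 / (n_true + n_decoy))
  expect_lt(abs(frac - 0.2), tol)
  ## strict parse through htslib; every record survives with its tags
  recs <- read_sam_records(fx$path[1])
  expect_equal(nrow(recs), 2 * (fx$true_pairs[1] + fx$decoy_pairs[1]))
  expect_equal(sum(!is.na(recs$decoy)), 2 * fx$decoy_pairs[1])
  expect_setequal(unique(stats::na.omit(recs$decoy)),
                  intersect(unique(stats::na.omit(recs$decoy)),
                            c("cross_genome", "low_identity", "short_align")))
})
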