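expr_from <- function(values) expression_matrix(values)

test_that("negligible-sample exclusion uses a strict threshold and rpoB zero", {
  ds <- simulate_dataset(small_sim_config(seed = 13))
  counts <- ds$counts$counts
  ## plant two dead libraries and one exactly-at-threshold sample
  phage <- ds$models$gene_id[ds$models$genome_id == "phage"]
  counts[, 1] <- 0L
  counts[phage, 2] <- 0L
  counts[, 3] <- 0L
  counts[phage[1], 3] <- 10L         # phage total == threshold
  counts["rpoB", 3] <- 5L
  cm <- count_matrix(counts)
  flags <- flag_negligible(cm, ds$models, min_total_pairs = 10)
  expect_identical(flags$sample[flags$excluded], colnames(counts)[1:2])
  expect_match(flags$reason[1], "negligible_phage")
  expect_match(flags$reason[1], "rpoB_zero")
  expect_match(flags$reason[2], "negligible_phage")
  expect_false(flags$excluded[3])    # threshold is strict less-than
})

test_that("the log2 marker ratio classifies states by sign", {
  v <- matrix(c(2, 1, 1,   1, 1, 1,   0.5, 4, 1), nrow = 3,
              dimnames = list(c("gp091", "gp135", "gp136"),
                              c("s1", "s2", "s3")))
  calls <- classify_state(expr_from(v))
  expect_equal(calls$log2_ratio[1], 1, tolerance = 0.2)   # eps-shifted
  expect_identical(calls$state, c("lytic", "indeterminate", "lysogenic"))
})

test_that("swapping marker roles negates ratios and swaps the calls", {
  ds <- simulate_dataset(small_sim_config(seed = 14))
  em <- rpob_normalize(ds$counts)
  fwd <- classify_state(em, marker_set("gp091", c("gp135", "gp136")))
  rev <- classify_state(em, marker_set("gp135", c("gp091", "gp136")))
  expect_equal(rev$log2_ratio, -fwd$log2_ratio)
  swapped <- c(lytic = "lysogenic", lysogenic = "lytic",
               indeterminate = "indeterminate")
  expect_identical(unname(swapped[fwd$state]), rev$state)
})

test_that("the ratio is insensitive to the normalisation route", {
  ds <- simulate_dataset(small_sim_config(seed = 15))
  r_lib1 <- classify_state(libsize_normalize(ds$counts, scale = 1e6))$log2_ratio
  r_lib2 <- classify_state(libsize_normalize(ds$counts, scale = 1))$log2_ratio
  r_rpob <- classify_state(rpob_normalize(ds$counts))$log2_ratio
  expect_equal(r_lib1, r_lib2)                       # scale cancels exactly
  expect_equal(r_lib1, r_rpob, tolerance = 0.1)      # rpoB cancels up to eps
})

test_that("with a zero tie band indeterminate calls have measure zero", {
  ds <- simulate_dataset(small_sim_config(n_samples = 40, seed = 16))
  calls <- classify_state(rpob_normalize(ds$counts))
  expect_false(any(calls$state == "indeterminate"))
})

test_that("planted states are recovered at high fold change", {
  cfg <- small_sim_config(n_samples = 40, state_fold_change = 10, seed = 19)
  ds <- simulate_dataset(cfg)
  calls <- classify_state(rpob_normalize(ds$counts))
  truth <- ds$truth$state_per_sample[calls$sample]
  expect_gte(mean(calls$state == truth), 0.9)
})

test_that("marker correlations report Pearson rho with t-based p", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v <- rbind(gp091 = x, gp135 = 2 * x, gp136 = c(2, 1, 4, 3, 6, 5, 8, 7))
  colnames(v) <- paste0("s", 1:8)
  out <- marker_correlations(expr_from(v))
  r1 <- out[out$gene1 == "gp091" & out$gene2 == "gp135", ]
  expect_equal(r1$rho, 1)
  expect_lt(r1$p_value, 1e-12)
  ## agreement with the classical per-pair test
  r2 <- out[out$gene1 == "gp091" & out$gene2 == "gp136", ]
  ct <- cor.test(x, v["gp136", ])
  expect_equal(r2$rho, unname(ct$estimate))
  expect_equal(r2$p_value, ct$p.value)
})

test_that("constant marker rows are flagged undefined, not given a rho", {
  v <- rbind(gp091 = rnorm(10), gp135 = rnorm(10), gp136 = rep(1, 10))
  colnames(v) <- paste0("s", 1:10)
  out <- marker_correlations(expr_from(v))
  bad <- out[out$gene2 == "gp136" | out$gene1 == "gp136", ]
  expect_true(all(bad$undefined))
  expect_true(all(is.na(bad$rho)))
  expect_error(marker_correlations(expr_from(v[, 1:2])),
               class = "phagestate_data_error")
})

test_that("permutation p-values track the t reference for moderate rho", {
  withr::with_seed(77, {
    x <- rnorm(33)
    y <- 0.5 * x + sqrt(0.75) * rnorm(33)
  })
  v <- rbind(gp091 = x, gp135 = y, gp136 = y + 0.01 * seq_along(y))
  colnames(v) <- paste0("s", 1:33)
  t_out <- marker_correlations(expr_from(v), method = "t")
  p_out <- marker_correlations(expr_from(v), method = "permutation",
                               n_perm = 1999, seed = 5)
  i <- 1
  expect_equal(p_out$p_value[i], t_out$p_value[i], tolerance = 0.02)
})
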