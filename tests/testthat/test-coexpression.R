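test_that("association matrix has unit diagonal and antipodal extremes", {
  withr::with_seed(1, {
    g1 <- rnorm(20)
    vals <- rbind(a = g1, b = -g1, c = rnorm(20))
  })
  colnames(vals) <- paste0("s", 1:20)
  assoc <- gene_association(vals)
  expect_equal(unname(diag(assoc$rho)), rep(1, 3))
  expect_equal(unname(assoc$rho["a", "b"]), -1)
  expect_equal(unname(assoc$d["a", "b"]), 2)
  expect_equal(unname(assoc$d["a", "a"]), 0)
})

test_that("zero-variance genes are dropped and too-few genes error", {
  vals <- rbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  colnames(vals) <- paste0("s", 1:10)
  expect_message(assoc <- gene_association(vals), "zero-variance")
  expect_identical(assoc$dropped, "b")
  expect_error(gene_association(rbind(a = rep(1, 10), b = rep(2, 10))),
               class = "phagestate_data_error")
})

test_that("the p <= 0.1 edge cutoff has calibrated type-I error under the null", {
  withr::with_seed(3, {
    vals <- matrix(rnorm(200 * 33), 200,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
  })
  assoc <- gene_association(vals)
  frac <- mean(lower_tri <- assoc$p[lower.tri(assoc$p)] <= 0.1)
  expect_gt(frac, 0.06)
  expect_lt(frac, 0.14)
})

test_that("perfectly correlated genes merge first at height zero", {
  withr::with_seed(4, {
    g <- rnorm(15)
    vals <- rbind(a = g, b = 2 * g + 3, c = rnorm(15))
  })
  colnames(vals) <- paste0("s", 1:15)
  tree <- cluster_genes(gene_association(vals))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("a", "b"))
  expect_lt(tree$height[1], 1e-12)
  expect_true(all(diff(tree$height) >= -1e-12))  # monotone merge heights
})

test_that("merge structure is invariant to input gene order", {
  bx <- block_expression(n_genes = 24, n_samples = 20, seed = 5)
  t1 <- cluster_genes(gene_association(bx$values))
  perm <- withr::with_seed(6, sample(nrow(bx$values)))
  t2 <- cluster_genes(gene_association(bx$values[perm, ]))
  c1 <- as.matrix(stats::cophenetic(t1))
  c2 <- as.matrix(stats::cophenetic(t2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2)
})

test_that("planted blocks are recovered at a k = 3 cut", {
  skip_if_not_installed("mclust")
  bx <- block_expression(n_genes = 60, n_samples = 33, rho = 0.8, seed = 7)
  tree <- cluster_genes(gene_association(bx$values))
  cut <- stats::cutree(tree, k = 3)
  ari <- mclust::adjustedRandIndex(cut[names(bx$block)], bx$block)
  expect_gte(ari, 0.9)
})

test_that("homogeneous branches collapse and heterogeneous ones do not", {
  withr::with_seed(8, {
    base <- rnorm(25)
    homo <- t(replicate(8, base + rnorm(25, sd = 0.4)))
    anti <- rbind(t(replicate(4, base + rnorm(25, sd = 0.3))),
                  t(replicate(4, -base + rnorm(25, sd = 0.3))))
  })
  rownames(homo) <- sprintf("h%02d", 1:8)
  colnames(homo) <- paste0("s", 1:25)
  rownames(anti) <- sprintf("a%02d", 1:8)
  colnames(anti) <- paste0("s", 1:25)

  th <- cluster_genes(gene_association(homo))
  gh <- collapse_indistinguishable(th, homo, n_perm = 199, seed = 9)
  expect_equal(length(unique(gh$group)), 1L)       # whole tree is one group
  expect_true(all(gh$collapsed))

  ta <- cluster_genes(gene_association(anti))
  ga <- collapse_indistinguishable(ta, anti, n_perm = 199, seed = 9)
  expect_gt(length(unique(ga$group)), 1L)          # root was rejected
  ## no collapsed group mixes the two anti-correlated halves
  for (grp in unique(ga$group[ga$collapsed])) {
    members <- ga$gene_id[ga$group == grp]
    expect_true(all(startsWith(members, "h")) || all(startsWith(members, "a")))
  }
})

test_that("collapse respects the hierarchy and the permutation floor", {
  bx <- block_expression(n_genes = 18, n_samples = 20, rho = 0.9, seed = 10)
  tree <- cluster_genes(gene_association(bx$values))
  expect_error(collapse_indistinguishable(tree, bx$values, n_perm = 50),
               class = "phagestate_config_error")
  grp <- collapse_indistinguishable(tree, bx$values, n_perm = 199, seed = 11)
  ## every gene lands in exactly one group (partition, no double counting)
  expect_equal(nrow(grp), 18L)
  expect_false(any(duplicated(grp$gene_id)))
})

test_that("cluster summaries report membership, markers and co-expression", {
  bx <- block_expression(n_genes = 30, n_samples = 25, rho = 0.8, seed = 12,
                         gene_names = c("gp135", "gp136", "gp091",
                                        sprintf("g%03d", 4:30)))
  ## genes 1,4,7,... are block 1 etc.: gp135/gp136 separate from gp091
  assoc <- gene_association(bx$values)
  tree <- cluster_genes(assoc)
  rep3 <- summarize_clusters(tree, assoc, k = 3)
  expect_equal(sum(rep3$summary$n_genes), 30)
  cl <- stats::setNames(rep3$assignment$cluster, rep3$assignment$gene_id)
  expect_equal(unname(cl["gp135"]), unname(cl[["g004"]]))  # same planted block
  expect_false(cl[["gp135"]] == cl[["gp091"]])
  rep1 <- summarize_clusters(tree, assoc, k = 1)
  expect_equal(rep1$summary$n_genes, 30)
  expect_error(summarize_clusters(tree, assoc, k = 40),
               class = "phagestate_config_error")
  ## independent genes: few significant co-expression partners
  withr::with_seed(13, {
    indep <- matrix(rnorm(20 * 30), 20,
                    dimnames = list(sprintf("i%02d", 1:20), NULL))
  })
  ai <- gene_association(indep)
  ti <- cluster_genes(ai)
  ri <- summarize_clusters(ti, ai, k = 1)
  expect_lt(ri$summary$n_coexpressed, 20)
})

test_that("dendrograms export as parseable Newick", {
  bx <- block_expression(n_genes = 10, n_samples = 15, seed = 14)
  tree <- cluster_genes(gene_association(bx$values))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(bx$values))
})
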