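## Whole-genome co-expression: gene-gene Pearson association, average-linkage
## hierarchical clustering on d = 1 - rho, a SIMPROF-style permutation test
## that collapses branches whose members' expression patterns are
## statistically indistinguishable, and a major-cluster report.

#' Gene-gene Pearson association matrix
#'
#' Symmetric Pearson correlation over genes with two-sided t-based p-values
#' and the clustering distance `d = 1 - rho` (range `[0, 2]`). Zero-variance
#' genes are removed first and reported.
#'
#' @param expr an [expression_matrix()] (genes in rows).
#' @return list `rho`, `p`, `d`, `n_samples`, `dropped` (ids of
#'   zero-variance genes), class `gene_association`.
#' @export
gene_association <- function(expr) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (ncol(vals) < 3L) stop_data("at least 3 samples are required")
  v <- apply(vals, 1L, stats::var)
  dropped <- rownames(vals)[v == 0]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  vals <- vals[v > 0, , drop = FALSE]
  if (nrow(vals) < 2L)
    stop_data("fewer than 2 non-constant genes; association is undefined")
  ct <- cor_with_pvalues(vals)
  structure(list(rho = ct$rho, p = ct$p, d = 1 - ct$rho,
                 n_samples = ct$n, dropped = dropped),
            class = "gene_association")
}

#' Agglomerative clustering of genes on 1 - rho
#'
#' Average (UPGMA) or complete linkage on the association distance. Genes
#' are ordered lexicographically before clustering so the merge structure is
#' deterministic and invariant to the input gene order.
#'
#' @param assoc a [gene_association()].
#' @param linkage `"average"` or `"complete"`.
#' @return an [stats::hclust] tree.
#' @export
cluster_genes <- function(assoc, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- assoc$d
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop_data("non-finite distance between genes ",
              rownames(d)[bad[1]], " and ", colnames(d)[bad[2]])
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = linkage)
}

## member leaf indices of every internal node of an hclust tree
node_members <- function(tree) {
  n <- nrow(tree$merge)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    m <- tree$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) -m[1] else members[[m[1]]],
                      if (m[2] < 0) -m[2] else members[[m[2]]])
  }
  members
}

## heterogeneity statistic: mean absolute deviation of the within-node
## pairwise correlations from their node mean
simprof_stat <- function(vals) {
  r <- lower_tri(suppressWarnings(stats::cor(t(vals))))
  r[is.na(r)] <- 0
  mean(abs(r - mean(r)))
}

#' Collapse statistically indistinguishable branches
#'
#' Top-down similarity-profile permutation test at each dendrogram node: the
#' observed statistic is the mean absolute deviation of the within-node
#' pairwise Pearson correlations from their mean; the null is built by
#' permuting each member gene's sample values independently (B = `n_perm`,
#' seeded). Nodes where internal heterogeneity is *not* detected
#' (permutation p > `alpha`) collapse into one group and their descendants
#' are not tested; detected-heterogeneous nodes recurse. Homogeneity is the
#' null, so under independent noise a node collapses with probability about
#' `1 - alpha`.
#'
#' @param tree an [stats::hclust] tree from [cluster_genes()].
#' @param expr the [expression_matrix()] (or matrix) the tree was built on.
#' @param alpha significance level for declaring heterogeneity.
#' @param n_perm permutations per node (>= 99).
#' @param seed RNG seed.
#' @return data frame `gene_id`, `group` (letter labels in tree order),
#'   `collapsed` (TRUE for tested, non-rejected multi-gene groups).
#' @export
collapse_indistinguishable <- function(tree, expr, alpha = 0.05,
                                       n_perm = 999, seed = 1) {
  if (n_perm < 99)
    stop_config("n_perm must be at least 99 for usable null resolution")
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  vals <- vals[tree$labels, , drop = FALSE]
  members <- node_members(tree)
  n_leaf <- length(tree$labels)
  group_of <- integer(n_leaf)
  collapsed_flag <- logical(0)
  next_group <- 0L
  with_seed(seed, {
    assign_group <- function(leaves, is_collapsed) {
      next_group <<- next_group + 1L
      group_of[leaves] <<- next_group
      collapsed_flag[next_group] <<- is_collapsed
    }
    test_node <- function(node) {
      if (node < 0) {                      # leaf
        assign_group(-node, FALSE)
        return(invisible())
      }
      leaves <- members[[node]]
      sub <- vals[leaves, , drop = FALSE]
      pi_obs <- simprof_stat(sub)
      pi_null <- replicate(n_perm, simprof_stat(
        t(apply(sub, 1L, sample))))
      p <- (1 + sum(pi_null >= pi_obs)) / (n_perm + 1)
      if (p > alpha) {
        assign_group(leaves, TRUE)         # indistinguishable: collapse
      } else {
        test_node(tree$merge[node, 1])
        test_node(tree$merge[node, 2])
      }
    }
    test_node(nrow(tree$merge))
  })
  labels <- make.unique(c(LETTERS, paste0(rep(LETTERS, each = 26),
                                          LETTERS)))[seq_len(next_group)]
  data.frame(gene_id = tree$labels,
             group = labels[group_of],
             collapsed = collapsed_flag[group_of],
             stringsAsFactors = FALSE)
}

#' Major-cluster summary
#'
#' Cuts the tree into `k` major clusters and reports, per cluster, the gene
#' membership, marker content, and the number of genes significantly
#' co-expressed (p <= `edge_p`) with at least one other member.
#'
#' @param tree an [stats::hclust] tree.
#' @param assoc the matching [gene_association()].
#' @param markers a [marker_set()] (optional).
#' @param k number of major clusters.
#' @param edge_p co-expression edge p-value cutoff (default 0.1).
#' @return list with `assignment` (gene_id, cluster) and `summary` (one row
#'   per cluster), class `cluster_report`.
#' @export
summarize_clusters <- function(tree, assoc, markers = marker_set(), k = 3,
                               edge_p = 0.1) {
  if (k > length(tree$labels))
    stop_config("k exceeds the number of genes")
  cl <- stats::cutree(tree, k = k)
  marker_genes <- c(markers$lytic_marker, markers$lysogeny_markers)
  rows <- lapply(sort(unique(cl)), function(ci) {
    genes <- names(cl)[cl == ci]
    p_sub <- assoc$p[genes, genes, drop = FALSE]
    diag(p_sub) <- NA
    n_coexpr <- sum(apply(p_sub, 1L, function(r) any(r <= edge_p, na.rm = TRUE)))
    data.frame(cluster = ci, n_genes = length(genes),
               markers = paste(intersect(marker_genes, genes), collapse = ","),
               n_coexpressed = n_coexpr, stringsAsFactors = FALSE)
  })
  structure(list(assignment = data.frame(gene_id = names(cl), cluster = unname(cl),
                                         stringsAsFactors = FALSE),
                 summary = do.call(rbind, rows), k = k, edge_p = edge_p),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report: k =", x$k, "\n")
  print(x$summary)
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' @param tree an [stats::hclust] tree.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
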