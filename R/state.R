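## Marker-ratio state classifier: the dominant infection state of each
## sample is called from the log2 ratio of lytic (tail sheath, gp091) to
## lysogenic (IS607 transposase gp135 / serine recombinase gp136) marker
## expression.

#' Marker gene set
#'
#' @param lytic_marker the lytic-cycle marker (tail sheath), default gp091.
#' @param lysogeny_markers lysogeny markers, primary first (IS607
#'   transposase gp135, then serine recombinase gp136).
#' @return a `marker_set`.
#' @export
marker_set <- function(lytic_marker = "gp091",
                       lysogeny_markers = c("gp135", "gp136")) {
  structure(list(lytic_marker = lytic_marker,
                 lysogeny_markers = lysogeny_markers),
            class = "marker_set")
}

check_markers <- function(markers, genes) {
  need <- c(markers$lytic_marker, markers$lysogeny_markers)
  miss <- setdiff(need, genes)
  if (length(miss))
    stop_config("marker gene(s) missing from the matrix: ",
                paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Flag samples with negligible expression
#'
#' A sample is excluded iff its total phage-gene pair count is strictly
#' below `min_total_pairs`, or its rpoB count is zero. Excluded samples are
#' dropped from all downstream stages.
#'
#' @param counts a [count_matrix()].
#' @param models a [gene_model_set()] identifying the phage genes.
#' @param rpoB_gene host rpoB row name.
#' @param min_total_pairs exclusion threshold (strict less-than), default 10
#'   -- the smallest count at which a marker ratio has any resolution.
#' @return data frame `sample`, `excluded`, `reason` (comma-joined).
#' @export
flag_negligible <- function(counts, models, rpoB_gene = "rpoB",
                            min_total_pairs = 10) {
  phage_genes <- intersect(models$gene_id[models$genome_id == "phage"],
                           rownames(counts$counts))
  phage_total <- colSums(counts$counts[phage_genes, , drop = FALSE])
  rp <- if (rpoB_gene %in% rownames(counts$counts))
    counts$counts[rpoB_gene, ] else stop_config("rpoB gene absent")
  low_phage <- phage_total < min_total_pairs
  no_host <- rp == 0
  reason <- mapply(function(a, b)
    paste(c(if (a) "negligible_phage", if (b) "rpoB_zero"), collapse = ","),
    low_phage, no_host)
  data.frame(sample = colnames(counts$counts),
             excluded = low_phage | no_host,
             reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Classify per-sample lytic vs lysogenic state
#'
#' Computes `log2_ratio = log2((lytic + eps) / (lysogeny + eps))` on the
#' (normalised) marker rows, with `eps` half the smallest nonzero value in
#' the matrix so that zero-vs-zero gives ratio 0, and calls the state:
#' lytic if the ratio exceeds `tie_band`, lysogenic below `-tie_band`,
#' indeterminate within the band. The secondary lysogeny marker's ratio is
#' reported alongside.
#'
#' @param expr an [expression_matrix()], rpoB- or library-size-normalised.
#' @param markers a [marker_set()].
#' @param tie_band half-width of the indeterminate band on the log2 scale.
#' @return a `state_calls` data frame: `sample`, `log2_ratio`,
#'   `log2_ratio_secondary`, `state`.
#' @export
classify_state <- function(expr, markers = marker_set(), tie_band = 0) {
  vals <- expr$values
  check_markers(markers, rownames(vals))
  nz <- vals[vals > 0]
  eps <- if (length(nz)) min(nz) / 2 else 0.5
  e_lyt <- vals[markers$lytic_marker, ]
  e_lys <- vals[markers$lysogeny_markers[1], ]
  ratio <- log2((e_lyt + eps) / (e_lys + eps))
  ratio2 <- if (length(markers$lysogeny_markers) > 1L)
    log2((e_lyt + eps) / (vals[markers$lysogeny_markers[2], ] + eps))
  else rep(NA_real_, length(ratio))
  state <- ifelse(ratio > tie_band, "lytic",
                  ifelse(ratio < -tie_band, "lysogenic", "indeterminate"))
  structure(
    data.frame(sample = colnames(vals), log2_ratio = ratio,
               log2_ratio_secondary = ratio2, state = state,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("state_calls", "data.frame")
  )
}

#' Pairwise marker correlations
#'
#' Pearson correlation between every pair of marker genes on
#' log2(x + 10)-transformed absolute abundances, with two-sided p-values
#' from the t reference distribution (or a seeded permutation null).
#' Constant marker rows yield an explicitly flagged undefined correlation.
#'
#' @param expr an [expression_matrix()] of log2(x + 10)-transformed counts.
#' @param markers a [marker_set()].
#' @param method `"t"` (classical Pearson test) or `"permutation"`.
#' @param n_perm,seed permutation-null settings.
#' @return data frame `gene1`, `gene2`, `rho`, `p_value`, `n`, `undefined`.
#' @export
marker_correlations <- function(expr, markers = marker_set(),
                                method = c("t", "permutation"),
                                n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  vals <- expr$values
  check_markers(markers, rownames(vals))
  if (ncol(vals) < 3L) stop_data("at least 3 retained samples are required")
  genes <- c(markers$lytic_marker, markers$lysogeny_markers)
  combs <- utils::combn(genes, 2L)
  out <- lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1L, i]; g2 <- combs[2L, i]
    r <- pearson_pair_test(vals[g1, ], vals[g2, ], method = method,
                           n_perm = n_perm, seed = seed)
    data.frame(gene1 = g1, gene2 = g2, rho = r$rho, p_value = r$p,
               n = r$n, undefined = r$undefined, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write state calls as TSV
#'
#' @param calls a `state_calls` data frame.
#' @param path TSV path.
#' @export
write_state_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
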