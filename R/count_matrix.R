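#' Gene-by-sample read-pair count matrix
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns (both dimnames required).
#' @param library_size per-sample total retained read pairs; defaults to the
#'   column sums.
#' @param intergenic per-sample tally of retained pairs overlapping no ORF.
#' @param provenance list recording the filter parameters that produced the
#'   matrix.
#' @return a `count_matrix`.
#' @export
count_matrix <- function(counts, library_size = NULL, intergenic = NULL,
                         provenance = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_data("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_data("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(intergenic))
    intergenic <- stats::setNames(integer(ncol(counts)), colnames(counts))
  if (is.null(library_size))
    library_size <- colSums(counts) + intergenic
  library_size <- stats::setNames(as.numeric(library_size), colnames(counts))
  if (any(colSums(counts) > library_size))
    stop_data("column sums may not exceed library_size")
  structure(
    list(counts = counts, library_size = library_size,
         intergenic = intergenic, provenance = provenance),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      "median library size", stats::median(x$library_size), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' Genes as rows, samples as columns; library sizes and the intergenic tally
#' are stored as two trailing annotation rows (`__library_size`,
#' `__intergenic`).
#'
#' @param x a [count_matrix()].
#' @param path TSV path.
#' @return `read_counts` returns a [count_matrix()].
#' @export
write_counts <- function(x, path) {
  tab <- rbind(x$counts,
               `__library_size` = x$library_size,
               `__intergenic` = x$intergenic)
  df <- data.frame(gene_id = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ann <- c("__library_size", "__intergenic")
  libs <- if ("__library_size" %in% rownames(m)) m["__library_size", ] else NULL
  inter <- if ("__intergenic" %in% rownames(m)) as.integer(m["__intergenic", ]) else NULL
  if (!is.null(inter)) names(inter) <- colnames(m)
  m <- m[!rownames(m) %in% ann, , drop = FALSE]
  count_matrix(m, library_size = libs, intergenic = inter,
               provenance = list(source = path))
}

#' Drop samples from a count matrix
#'
#' @param x a [count_matrix()].
#' @param samples sample names to remove.
#' @export
drop_samples <- function(x, samples) {
  keep <- setdiff(colnames(x$counts), samples)
  if (!length(keep)) stop_data("dropping all samples")
  count_matrix(x$counts[, keep, drop = FALSE],
               library_size = x$library_size[keep],
               intergenic = x$intergenic[keep],
               provenance = c(x$provenance, list(dropped = samples)))
}
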