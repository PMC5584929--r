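#' Provenance-tagged expression matrix
#'
#' A real-valued gene-by-sample matrix together with the ordered chain of
#' transforms that produced it, so any derived matrix can be reproduced
#' bit-identically from its source counts via [replay_transforms()].
#'
#' @param values numeric matrix, genes in rows.
#' @param transform_chain list of `list(name, params)` entries, oldest first.
#' @param flagged data frame of excluded samples and reasons.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, transform_chain = list(),
                              flagged = NULL) {
  values <- as.matrix(values)
  if (is.null(flagged))
    flagged <- data.frame(sample = character(), reason = character())
  structure(list(values = values, transform_chain = transform_chain,
                 flagged = flagged),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  chain <- vapply(x$transform_chain, `[[`, "", "name")
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; chain:", paste(chain, collapse = " -> "), "\n")
  invisible(x)
}

append_transform <- function(m, name, params = list()) {
  m$transform_chain <- c(m$transform_chain, list(list(name = name,
                                                      params = params)))
  m
}

#' Library-size normalisation (pairs per `scale` pairs)
#'
#' `value(g, s) = counts(g, s) / library_size(s) * scale`. Samples with zero
#' library size cannot be normalised and are excluded with a logged reason.
#'
#' @param counts a [count_matrix()].
#' @param scale scale factor, default 1e6 (per-million); the scale cancels in
#'   every downstream ratio and resemblance.
#' @return an [expression_matrix()].
#' @export
libsize_normalize <- function(counts, scale = 1e6) {
  libs <- counts$library_size
  bad <- names(libs)[libs == 0]
  if (length(bad)) {
    warning("excluding sample(s) with zero library size: ",
            paste(bad, collapse = ", "), call. = FALSE)
    counts <- drop_samples(counts, bad)
    libs <- counts$library_size
  }
  vals <- sweep(counts$counts, 2L, libs, "/") * scale
  m <- expression_matrix(vals,
                         flagged = data.frame(sample = bad,
                                              reason = rep("zero_library", length(bad))))
  append_transform(m, "libsize_normalize", list(scale = scale))
}

#' Host rpoB normalisation
#'
#' Divides every gene's counts by the host RNA-polymerase-B gene's counts in
#' the same sample, a proxy for host cell density. Samples where rpoB is
#' zero are not normalisable and are excluded with a logged reason.
#'
#' @param counts a [count_matrix()].
#' @param rpoB_gene name of the rpoB row.
#' @return an [expression_matrix()].
#' @export
rpob_normalize <- function(counts, rpoB_gene = "rpoB") {
  if (!rpoB_gene %in% rownames(counts$counts))
    stop_config("rpoB gene '", rpoB_gene, "' absent from the count matrix")
  rp <- counts$counts[rpoB_gene, ]
  bad <- names(rp)[rp == 0]
  if (length(bad)) {
    warning("excluding sample(s) with zero rpoB count: ",
            paste(bad, collapse = ", "), call. = FALSE)
    counts <- drop_samples(counts, bad)
    rp <- counts$counts[rpoB_gene, ]
  }
  vals <- sweep(counts$counts, 2L, rp, "/")
  m <- expression_matrix(vals,
                         flagged = data.frame(sample = bad,
                                              reason = rep("rpoB_zero", length(bad))))
  append_transform(m, "rpob_normalize", list(rpoB_gene = rpoB_gene))
}

#' log2(x + 10) transform
#'
#' @param x non-negative numeric vector/matrix, or an [expression_matrix()].
#' @return same shape as the input; for an expression matrix the transform is
#'   appended to the chain.
#' @export
log2_shift <- function(x) UseMethod("log2_shift")

#' @export
log2_shift.default <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop_data("log2_shift requires x >= 0")
  log2(x + 10)
}

#' @export
log2_shift.expression_matrix <- function(x) {
  x$values <- log2_shift.default(x$values)
  append_transform(x, "log2_shift")
}

#' @export
log2_shift.count_matrix <- function(x) {
  m <- expression_matrix(log2_shift.default(x$counts))
  append_transform(m, "log2_shift")
}

#' Element-wise square-root transform
#'
#' @param m an [expression_matrix()] (or non-negative matrix).
#' @return transformed [expression_matrix()], chain appended.
#' @export
sqrt_transform <- function(m) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
  if (any(m$values < 0, na.rm = TRUE))
    stop_data("sqrt_transform requires non-negative values")
  m$values <- sqrt(m$values)
  append_transform(m, "sqrt_transform")
}

#' Replay a transform chain on source counts
#'
#' Re-applies a recorded transform chain to a [count_matrix()]; the result
#' is bit-identical to the matrix the chain was recorded from.
#'
#' @param counts source [count_matrix()].
#' @param chain a `transform_chain` from an [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
replay_transforms <- function(counts, chain) {
  m <- counts
  for (step in chain) {
    m <- switch(step$name,
      libsize_normalize = libsize_normalize(m, scale = step$params$scale),
      rpob_normalize = rpob_normalize(m, rpoB_gene = step$params$rpoB_gene),
      log2_shift = log2_shift(m),
      sqrt_transform = sqrt_transform(m),
      stop_config("unknown transform: ", step$name))
  }
  m
}

#' Write / read an expression matrix with its transform chain
#'
#' The values go to a TSV; the transform chain to a YAML sidecar
#' (`<path>.meta.yaml`), so provenance round-trips through serialization.
#'
#' @param m an [expression_matrix()].
#' @param path TSV path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(transform_chain = m$transform_chain),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta_path <- paste0(path, ".meta.yaml")
  chain <- if (file.exists(meta_path))
    yaml::read_yaml(meta_path)$transform_chain else list()
  expression_matrix(vals, transform_chain = chain)
}
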