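#' Gene model set
#'
#' A table of non-overlapping ORF intervals on named genomes, the coordinate
#' convention being 0-based half-open throughout (GFF3 input is converted on
#' read). Each gene may carry a `block` annotation (its co-expression block
#' in synthetic data, or `"host"` for host genes).
#'
#' @param genome_id character, genome of each gene.
#' @param gene_id character, unique gene identifiers.
#' @param start,end integer, 0-based half-open interval per gene.
#' @param strand `"+"` or `"-"`.
#' @param block optional block/role annotation per gene.
#' @param genome_length optional named vector of genome lengths (needed to
#'   emit SAM headers).
#' @return a `gene_model_set`, a data frame with one row per gene.
#' @export
gene_model_set <- function(genome_id, gene_id, start, end,
                           strand = "+", block = NA_character_,
                           genome_length = NULL) {
  df <- data.frame(
    genome_id = as.character(genome_id),
    gene_id = as.character(gene_id),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(gene_id)),
    block = rep_len(as.character(block), length(gene_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id))
    stop_data("gene_ids must be unique across the set")
  if (any(df$start < 0L) || any(df$start >= df$end))
    stop_data("gene intervals must satisfy 0 <= start < end")
  for (g in unique(df$genome_id)) {
    sub <- df[df$genome_id == g, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop_data("overlapping gene intervals on genome ", g,
                " (ambiguous models are rejected)")
  }
  if (is.null(genome_length)) {
    genome_length <- tapply(df$end, df$genome_id, max) + 200L
    genome_length <- stats::setNames(as.integer(genome_length), names(genome_length))
  }
  attr(df, "genome_length") <- genome_length
  class(df) <- c("gene_model_set", "data.frame")
  df
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x), "genes on",
      length(unique(x$genome_id)), "genome(s)\n")
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more genes\n")
  invisible(x)
}

as_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$genome_id,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand,
    gene_id = models$gene_id,
    block = models$block
  )
}

#' Read gene models from GFF3 or BED
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' (GFF3 is 1-based inclusive; BED is already 0-based half-open).
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"` (guessed from the extension by default).
#' @return a [gene_model_set()].
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  gid <- if (!is.null(mc$gene_id)) mc$gene_id
         else if (!is.null(mc$ID)) mc$ID
         else if (!is.null(mc$name)) mc$name
         else if (!is.null(mc$Name)) mc$Name
         else stop_data("no gene identifiers found in ", path)
  blk <- if (!is.null(mc$block)) as.character(mc$block) else NA_character_
  gene_model_set(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(gid),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    block = blk
  )
}

#' Write gene models to GFF3 or BED
#'
#' @param models a [gene_model_set()].
#' @param path destination path.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_gene_models <- function(models, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- as_granges(models)
  if (format == "gff3") {
    S4Vectors::mcols(gr)$ID <- models$gene_id
    S4Vectors::mcols(gr)$type <- "gene"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr) <- NULL
    names(gr) <- models$gene_id
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
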