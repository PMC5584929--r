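## Shared fixture builders. Everything is generated in code at test time.

small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 8, n_phage_genes = 30, n_host_genes = 4,
         library_size_range = c(1500, 3000), seed = seed),
    list(...))
  do.call(sim_config, args)
}

## expression matrix with b planted blocks: x_g = sqrt(rho) f_block +
## sqrt(1 - rho) noise, so within-block correlation is rho in expectation
block_expression <- function(n_genes = 60, n_samples = 33, n_blocks = 3,
                             rho = 0.8, seed = 1, gene_names = NULL) {
  withr::with_seed(seed, {
    block <- rep(seq_len(n_blocks), length.out = n_genes)
    f <- matrix(rnorm(n_blocks * n_samples), n_blocks)
    x <- sqrt(rho) * f[block, ] +
      sqrt(1 - rho) * matrix(rnorm(n_genes * n_samples), n_genes)
    rownames(x) <- gene_names %||% sprintf("g%03d", seq_len(n_genes))
    colnames(x) <- sprintf("s%02d", seq_len(n_samples))
    list(values = x, block = stats::setNames(block, rownames(x)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent brute-force BIOENV enumerator used as the oracle: plain loops
## over combn, dist() on the z-scored subset, cor(..., method = "spearman").
brute_force_bioenv <- function(dm, env, max_size) {
  z <- scale(as.matrix(env))
  dvec <- as.vector(stats::as.dist(dm))
  best <- list(rho = -Inf, subset = character(0))
  for (k in seq_len(max_size)) {
    for (idx in utils::combn(ncol(z), k, simplify = FALSE)) {
      e <- as.vector(stats::dist(z[, idx, drop = FALSE]))
      rho <- stats::cor(e, dvec, method = "spearman")
      if (rho > best$rho)
        best <- list(rho = rho, subset = colnames(z)[idx])
    }
  }
  best
}

## minimal alignment-record data frame for filter/pairing unit tests
rec <- function(read_id, mate, genome = "phage", start = 0L,
                alen = 125L, rlen = 125L, mm = 0L, mapped = TRUE,
                ref_width = alen) {
  data.frame(read_id = read_id, mate = mate, genome_id = genome,
             start = start, aligned_length = alen, read_length = rlen,
             ref_width = ref_width, mismatches = mm, mapped = mapped,
             decoy = NA_character_, source_gene = NA_character_,
             stringsAsFactors = FALSE)
}

## hand-written SAM file from record lines (adds a two-genome header)
write_toy_sam <- function(lines, phage_len = 10000L, host_len = 5000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:phage\tLN:%d", phage_len),
               sprintf("@SQ\tSN:host\tLN:%d", host_len),
               lines), path)
  path
}
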