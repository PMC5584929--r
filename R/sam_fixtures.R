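## Paired-end SAM fixture emission for filter and round-trip testing.
## Every counted pair becomes a properly paired record pair with both mates
## inside the source ORF; decoy pairs (cross-genome, low-identity, short
## alignment) are tagged with their truth label in the optional ZD attribute
## so filter accounting needs no side file.

DECOY_TYPES <- c("cross_genome", "low_identity", "short_align")

sam_header <- function(models) {
  gl <- attr(models, "genome_length")
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(gl), as.integer(gl)))
}

## one properly-paired record pair fully inside [gstart, gend) (0-based)
pair_records <- function(read_id, genome, gstart, gend, read_len, frag_len,
                         nm1, nm2, cigar1 = NULL, cigar2 = NULL, extra = "") {
  fstart <- gstart + sample.int(gend - gstart - frag_len + 1L, 1L) - 1L
  p1 <- fstart + 1L                      # SAM is 1-based
  p2 <- fstart + frag_len - read_len + 1L
  cigar1 <- cigar1 %||% paste0(read_len, "M")
  cigar2 <- cigar2 %||% paste0(read_len, "M")
  c(
    paste(read_id, 99L, genome, p1, 60L, cigar1, "=", p2, frag_len,
          "*", "*", paste0("NM:i:", nm1), extra, sep = "\t"),
    paste(read_id, 147L, genome, p2, 60L, cigar2, "=", p1, -frag_len,
          "*", "*", paste0("NM:i:", nm2), extra, sep = "\t")
  )
}

#' Emit per-sample paired-end SAM fixtures
#'
#' Writes one SAM file per sample reproducing the given counts: for every
#' counted pair, both mates are placed inside the source ORF with full-length
#' match CIGARs and an NM tag reflecting injected substitutions (binomial at
#' `seq_error_rate`). Genes shorter than the read length are skipped with a
#' warning. A `decoy_fraction` of additional pairs is emitted that must be
#' rejected by the quantification filters; each decoy carries its truth label
#' in the `ZD` tag, and every true pair carries its source gene in `ZG`.
#'
#' @param counts a [count_matrix()].
#' @param models the [gene_model_set()] the counts refer to.
#' @param config a [sim_config()] (read length, error rate, decoy fraction,
#'   seed).
#' @param dir output directory, created if needed.
#' @return data frame with one row per sample: `sample`, `path`,
#'   `true_pairs`, `decoy_pairs`.
#' @export
emit_read_fixtures <- function(counts, models, config, dir) {
  validate_sim_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- config$read_length
  glen <- models$end - models$start
  phage_genes <- models$gene_id[models$genome_id == "phage" & glen >= 2L * rl]
  host_genes <- models$gene_id[models$genome_id == "host" & glen >= 2L * rl]
  hdr <- sam_header(models)
  idx <- stats::setNames(seq_len(nrow(models)), models$gene_id)

  with_seed(config$seed + 3L, {
    out <- lapply(colnames(counts$counts), function(s) {
      lines <- character(0)
      rid <- 0L
      n_true <- 0L
      for (g in rownames(counts$counts)) {
        cnt <- counts$counts[g, s]
        if (cnt == 0L) next
        i <- idx[[g]]
        gl_i <- glen[i]
        if (gl_i < rl) {
          warning("gene ", g, " shorter than read length; skipped",
                  call. = FALSE)
          next
        }
        for (k in seq_len(cnt)) {
          rid <- rid + 1L
          frag <- sample(seq.int(min(2L * rl, gl_i), min(gl_i, 500L)), 1L)
          nm <- stats::rbinom(2L, rl, config$seq_error_rate)
          lines <- c(lines, pair_records(
            sprintf("%s_r%06d", s, rid), models$genome_id[i],
            models$start[i], models$end[i], rl, frag, nm[1], nm[2],
            extra = paste0("ZG:Z:", g)))
          n_true <- n_true + 1L
        }
      }
      ## decoys: each emitted pair is a decoy with probability decoy_fraction
      n_decoy <- if (config$decoy_fraction > 0 && n_true > 0)
        stats::rbinom(1L, n_true,
                      config$decoy_fraction / (1 - config$decoy_fraction))
      else 0L
      if (n_decoy > 0L) {
        types <- sample(DECOY_TYPES, n_decoy, replace = TRUE)
        for (k in seq_len(n_decoy)) {
          rid <- rid + 1L
          id <- sprintf("%s_d%06d", s, rid)
          g1 <- sample(phage_genes, 1L)
          i1 <- idx[[g1]]
          tag <- paste0("ZD:Z:", types[k])
          rec <- switch(
            types[k],
            cross_genome = {
              i2 <- idx[[sample(host_genes, 1L)]]
              p1 <- models$start[i1] + sample.int(glen[i1] - rl + 1L, 1L)
              p2 <- models$start[i2] + sample.int(glen[i2] - rl + 1L, 1L)
              c(paste(id, 97L, "phage", p1, 60L, paste0(rl, "M"), "host", p2,
                      0L, "*", "*", "NM:i:0", tag, sep = "\t"),
                paste(id, 145L, "host", p2, 60L, paste0(rl, "M"), "phage", p1,
                      0L, "*", "*", "NM:i:0", tag, sep = "\t"))
            },
            low_identity = {
              nm_bad <- ceiling(0.15 * rl)   # identity 0.85 < 0.9
              pair_records(id, "phage", models$start[i1], models$end[i1],
                           rl, min(2L * rl, glen[i1]), nm_bad, nm_bad,
                           extra = tag)
            },
            short_align = {
              al <- floor(0.8 * rl)          # length fraction 0.8 < 0.9
              cg <- paste0(al, "M", rl - al, "S")
              pair_records(id, "phage", models$start[i1], models$end[i1],
                           rl, min(2L * rl, glen[i1]), 0L, 0L,
                           cigar1 = cg, cigar2 = cg, extra = tag)
            })
          lines <- c(lines, rec)
        }
      }
      path <- file.path(dir, paste0(s, ".sam"))
      writeLines(c(hdr, lines), path)
      data.frame(sample = s, path = path, true_pairs = n_true,
                 decoy_pairs = n_decoy, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
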