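## Competitive read-pair quantification: SAM records are filtered on aligned
## length fraction and identity fraction, resolved to a single best hit per
## mate, screened so both mates of a pair map to the same genome, and counted
## against non-overlapping ORF models.

#' Read alignment records from a SAM file
#'
#' Parses a SAM file (through `Rsamtools`) into a flat record table with the
#' quantities the filters operate on: aligned length (query bases aligned,
#' soft clips excluded), read length, and mismatch count from the `NM` tag
#' (inferred from `MD` when `NM` is absent; records with neither are
#' rejected, as are records whose hard clips cover more than half the read).
#'
#' @param path SAM file path.
#' @return data frame with columns `read_id`, `mate`, `genome_id`, `start`
#'   (0-based), `aligned_length`, `read_length`, `ref_width`, `mismatches`,
#'   `mapped`, `decoy`, `source_gene`.
#' @export
read_sam_records <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("NM", "MD", "ZD", "ZG"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- b$cigar
  cigar[is.na(cigar)] <- "*"
  ok <- cigar != "*"
  alen <- rlen <- rwid <- integer(length(cigar))
  alen[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar[ok], after.soft.clipping = TRUE)
  rlen[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar[ok], after.soft.clipping = FALSE)
  rwid[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  ## hard clips covering > 50% of the read are malformed, not scored
  hard <- integer(length(cigar))
  if (any(ok)) {
    opl <- GenomicAlignments::explodeCigarOpLengths(cigar[ok], ops = "H")
    hard[ok] <- vapply(opl, sum, integer(1))
  }
  total_len <- rlen + hard
  malformed <- ok & total_len > 0L & hard > 0.5 * total_len

  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  md <- b$tag$MD
  if (!is.null(md)) {
    use_md <- is.na(nm) & !is.na(md)
    nm[use_md] <- vapply(md[use_md], md_mismatches, integer(1))
  }
  rejected <- malformed | (mapped & is.na(nm))
  if (any(rejected))
    warning(sum(rejected), " record(s) rejected as malformed ",
            "(oversized hard clips or no NM/MD tag)", call. = FALSE)

  zd <- b$tag$ZD %||% rep(NA_character_, length(flag))
  zg <- b$tag$ZG %||% rep(NA_character_, length(flag))
  df <- data.frame(
    read_id = b$qname,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    genome_id = as.character(b$rname),
    start = b$pos - 1L,
    aligned_length = alen,
    read_length = rlen,
    ref_width = rwid,
    mismatches = as.integer(nm),
    mapped = mapped,
    decoy = zd,
    source_gene = zg,
    stringsAsFactors = FALSE
  )
  df[!rejected, , drop = FALSE]
}

## mismatch count from an MD tag: matched bases are run lengths, mismatches
## single reference letters, deletions ^-prefixed letter runs (not mismatches)
md_mismatches <- function(md) {
  md <- gsub("\\^[A-Za-z]+", "", md)
  sum(nchar(gsub("[0-9]", "", md)))
}

#' Alignment length/identity filter
#'
#' A record passes iff `aligned_length / read_length >= min_length_fraction`
#' and `(aligned_length - mismatches) / aligned_length >=
#' min_identity_fraction`. Identity is computed over the aligned segment, not
#' the full read, matching the two cutoffs being stated separately.
#'
#' @param records alignment record data frame (see [read_sam_records()]).
#' @param min_length_fraction,min_identity_fraction cutoffs in `(0, 1]`,
#'   default 0.9 each.
#' @return logical vector, one element per record.
#' @export
passes_filters <- function(records, min_length_fraction = 0.9,
                           min_identity_fraction = 0.9) {
  if (min_length_fraction <= 0 || min_length_fraction > 1 ||
      min_identity_fraction <= 0 || min_identity_fraction > 1)
    stop_config("filter fractions must lie in (0, 1]")
  if (any(records$mapped & records$read_length == 0L))
    stop_data("malformed record: read_length of 0")
  alen <- records$aligned_length
  ok <- records$mapped & alen > 0L &
    alen / records$read_length >= min_length_fraction &
    (alen - records$mismatches) / alen >= min_identity_fraction
  ok & !is.na(ok)
}

#' Resolve competitive alignments to one best hit per mate
#'
#' Candidates sharing `(read_id, mate)` are scored as
#' `aligned_length - mismatches`; the unique best is kept. Ties are broken
#' uniformly at random under `random_best` (seeded) or the whole group is
#' discarded under `discard_ties`.
#'
#' @param records alignment record data frame (mapped candidates).
#' @param policy `"random_best"` or `"discard_ties"`.
#' @param seed RNG seed for tie-breaking.
#' @return data frame with at most one record per `(read_id, mate)`.
#' @export
resolve_competitive <- function(records, policy = c("random_best", "discard_ties"),
                                seed = 1) {
  policy <- match.arg(policy)
  records <- records[records$mapped, , drop = FALSE]
  if (!nrow(records)) return(records)
  score <- records$aligned_length - records$mismatches
  key <- paste(records$read_id, records$mate, sep = "\r")
  best <- stats::ave(score, key, FUN = max)
  top <- records[score == best, , drop = FALSE]
  keyt <- key[score == best]
  n_top <- table(keyt)
  if (policy == "discard_ties") {
    top[keyt %in% names(n_top)[n_top == 1L], , drop = FALSE]
  } else {
    with_seed(seed, {
      pick <- unlist(lapply(split(seq_len(nrow(top)), keyt), function(i)
        if (length(i) == 1L) i else sample(i, 1L)), use.names = FALSE)
      top[sort(pick), , drop = FALSE]
    })
  }
}

#' Pair mates and screen cross-genome pairs
#'
#' A pair is retained only if both mates resolved, both pass the filters,
#' and both map to the same genome. Exclusions are tallied by reason
#' (`orphan`, `filtered`, `cross_genome`).
#'
#' @param records resolved alignment records (at most one per mate).
#' @param pass logical vector from [passes_filters()] aligned with `records`.
#' @return list with `pairs` (one row per retained pair: `read_id`,
#'   `genome_id`, per-mate 0-based start/end) and `exclusions` (read_id,
#'   reason).
#' @export
pair_and_screen <- function(records, pass = passes_filters(records)) {
  ids <- unique(records$read_id)
  m1 <- match(paste(ids, 1L), paste(records$read_id, records$mate))
  m2 <- match(paste(ids, 2L), paste(records$read_id, records$mate))
  orphan <- is.na(m1) | is.na(m2) |
    !records$mapped[replace(m1, is.na(m1), 1L)] |
    !records$mapped[replace(m2, is.na(m2), 1L)]
  filtered <- !orphan & (!pass[m1] | !pass[m2])
  cross <- !orphan & !filtered &
    records$genome_id[m1] != records$genome_id[m2]
  keep <- !orphan & !filtered & !cross
  pairs <- data.frame(
    read_id = ids[keep],
    genome_id = records$genome_id[m1[keep]],
    start1 = records$start[m1[keep]],
    end1 = records$start[m1[keep]] + records$ref_width[m1[keep]],
    start2 = records$start[m2[keep]],
    end2 = records$start[m2[keep]] + records$ref_width[m2[keep]],
    decoy = records$decoy[m1[keep]],
    source_gene = records$source_gene[m1[keep]],
    stringsAsFactors = FALSE
  )
  reason <- c("orphan", "filtered", "cross_genome")[
    ifelse(orphan, 1L, ifelse(filtered, 2L, 3L))]
  exclusions <- data.frame(read_id = ids[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(pairs = pairs, exclusions = exclusions)
}

#' Count retained pairs against ORF models
#'
#' A pair increments a gene by exactly one if it satisfies the containment
#' rule: `both_within` (both mates inside the ORF; the default, a literal
#' pair-in-ORF reading), `fragment_within` (the outer fragment span inside),
#' or `any_overlap` (fragment overlaps the ORF; ties between adjacent ORFs
#' go to the larger overlap, then lexicographic gene id). Pairs matching no
#' ORF are tallied as intergenic.
#'
#' @param pairs data frame of retained pairs (see [pair_and_screen()]).
#' @param models a [gene_model_set()].
#' @param sample_names column layout of the resulting matrix.
#' @param sample_of named assignment of each pair's sample (defaults to a
#'   single sample).
#' @param containment containment rule.
#' @return a [count_matrix()] whose `library_size` is the number of retained
#'   pairs per sample and whose `intergenic` slot holds the out-of-ORF tally.
#' @export
count_pairs <- function(pairs, models, sample_names = "sample1",
                        sample_of = NULL,
                        containment = c("both_within", "fragment_within",
                                        "any_overlap")) {
  containment <- match.arg(containment)
  if (is.null(sample_of))
    sample_of <- rep(sample_names[1], nrow(pairs))
  genes_gr <- as_granges(models)
  assign_gene <- rep(NA_character_, nrow(pairs))
  if (nrow(pairs)) {
    frag <- GenomicRanges::GRanges(
      pairs$genome_id,
      IRanges::IRanges(start = pmin(pairs$start1, pairs$start2) + 1L,
                       end = pmax(pairs$end1, pairs$end2)))
    if (containment == "both_within") {
      r1 <- GenomicRanges::GRanges(pairs$genome_id,
              IRanges::IRanges(pairs$start1 + 1L, pairs$end1))
      r2 <- GenomicRanges::GRanges(pairs$genome_id,
              IRanges::IRanges(pairs$start2 + 1L, pairs$end2))
      h1 <- GenomicRanges::findOverlaps(r1, genes_gr, type = "within")
      h2 <- GenomicRanges::findOverlaps(r2, genes_gr, type = "within")
      k1 <- stats::setNames(S4Vectors::subjectHits(h1), S4Vectors::queryHits(h1))
      k2 <- stats::setNames(S4Vectors::subjectHits(h2), S4Vectors::queryHits(h2))
      same <- intersect(names(k1), names(k2))
      same <- same[k1[same] == k2[same]]
      assign_gene[as.integer(same)] <- models$gene_id[k1[same]]
    } else if (containment == "fragment_within") {
      h <- GenomicRanges::findOverlaps(frag, genes_gr, type = "within")
      assign_gene[S4Vectors::queryHits(h)] <-
        models$gene_id[S4Vectors::subjectHits(h)]
    } else {
      h <- GenomicRanges::findOverlaps(frag, genes_gr)
      if (length(h)) {
        ov <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(frag)[S4Vectors::queryHits(h)],
          IRanges::ranges(genes_gr)[S4Vectors::subjectHits(h)]))
        hd <- data.frame(q = S4Vectors::queryHits(h),
                         g = models$gene_id[S4Vectors::subjectHits(h)],
                         ov = ov)
        hd <- hd[order(hd$q, -hd$ov, hd$g), ]
        hd <- hd[!duplicated(hd$q), ]
        assign_gene[hd$q] <- hd$g
      }
    }
  }
  counts <- matrix(0L, nrow(models), length(sample_names),
                   dimnames = list(models$gene_id, sample_names))
  hit <- !is.na(assign_gene)
  if (any(hit)) {
    tab <- table(factor(assign_gene[hit], models$gene_id),
                 factor(sample_of[hit], sample_names))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  intergenic <- as.integer(table(factor(sample_of[!hit], sample_names)))
  names(intergenic) <- sample_names
  libsize <- as.integer(table(factor(sample_of, sample_names)))
  count_matrix(counts, library_size = libsize, intergenic = intergenic,
               provenance = list(containment = containment))
}

#' Quantify per-sample SAM files into a count matrix
#'
#' End-to-end competitive quantification: parse, filter (0.9/0.9 by
#' default), resolve each mate to its single best hit, drop orphaned,
#' filtered and cross-genome pairs, and count pair-in-ORF hits.
#'
#' @param sam_paths named character vector, one SAM path per sample.
#' @param models a [gene_model_set()].
#' @param min_length_fraction,min_identity_fraction filter cutoffs.
#' @param tie_policy competitive tie policy, see [resolve_competitive()].
#' @param containment pair-in-ORF rule, see [count_pairs()].
#' @param seed RNG seed for tie-breaking.
#' @return a [count_matrix()]; the per-sample exclusion audit is attached in
#'   `provenance$exclusions`.
#' @export
quantify_sam <- function(sam_paths, models,
                         min_length_fraction = 0.9,
                         min_identity_fraction = 0.9,
                         tie_policy = "random_best",
                         containment = "both_within",
                         seed = 1) {
  if (is.null(names(sam_paths)))
    names(sam_paths) <- sub("\\.sam$", "", basename(sam_paths))
  samples <- names(sam_paths)
  all_pairs <- list()
  all_sample <- list()
  audit <- list()
  for (s in samples) {
    rec <- read_sam_records(sam_paths[[s]])
    res <- resolve_competitive(rec, tie_policy, seed = seed)
    ps <- pair_and_screen(res, passes_filters(res, min_length_fraction,
                                              min_identity_fraction))
    all_pairs[[s]] <- ps$pairs
    all_sample[[s]] <- rep(s, nrow(ps$pairs))
    if (nrow(ps$exclusions))
      audit[[s]] <- cbind(sample = s, ps$exclusions)
  }
  pairs <- do.call(rbind, all_pairs)
  out <- count_pairs(pairs, models, sample_names = samples,
                     sample_of = unlist(all_sample, use.names = FALSE),
                     containment = containment)
  out$provenance <- list(
    min_length_fraction = min_length_fraction,
    min_identity_fraction = min_identity_fraction,
    tie_policy = tie_policy, containment = containment, seed = seed,
    exclusions = if (length(audit)) do.call(rbind, audit)
                 else data.frame(sample = character(), read_id = character(),
                                 reason = character())
  )
  out
}

#' Write the exclusion audit as TSV
#'
#' @param counts a [count_matrix()] from [quantify_sam()].
#' @param path TSV path.
#' @export
write_exclusion_audit <- function(counts, path) {
  utils::write.table(counts$provenance$exclusions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
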