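test_that("length and identity fractions gate records as stated", {
  r <- rbind(rec("a", 1, alen = 125, rlen = 125, mm = 5),    # id 0.96
             rec("b", 1, alen = 100, rlen = 125, mm = 0),    # len 0.8
             rec("c", 1, alen = 125, rlen = 125, mm = 13),   # id 112/125
             rec("d", 1, alen = 113, rlen = 125, mm = 11))   # len .904, id .9027
  expect_identical(passes_filters(r), c(TRUE, FALSE, FALSE, TRUE))
  ## boundaries are >=: exactly 0.9 on both fractions passes
  r2 <- rec("e", 1, alen = 113, rlen = 125, mm = 12)  # len 0.904, id 0.8938
  expect_false(passes_filters(r2))
  expect_error(passes_filters(r, min_length_fraction = 0),
               class = "phagestate_config_error")
  expect_error(passes_filters(rec("f", 1, rlen = 0L, alen = 0L)),
               class = "phagestate_data_error")
})

test_that("competitive resolution keeps the unique best and honours tie policy", {
  r <- rbind(rec("a", 1, genome = "phage", alen = 125, mm = 5),   # score 120
             rec("a", 1, genome = "host", alen = 125, mm = 7))    # score 118
  for (pol in c("random_best", "discard_ties")) {
    out <- resolve_competitive(r, pol)
    expect_equal(nrow(out), 1L)
    expect_equal(out$genome_id, "phage")
  }
  tie <- rbind(rec("a", 1, genome = "phage"), rec("a", 1, genome = "host"))
  expect_equal(nrow(resolve_competitive(tie, "discard_ties")), 0L)
  pick <- resolve_competitive(tie, "random_best", seed = 4)
  expect_equal(nrow(pick), 1L)
  expect_identical(pick, resolve_competitive(tie, "random_best", seed = 4))
  expect_equal(nrow(resolve_competitive(rec("x", 1, mapped = FALSE))), 0L)
})

test_that("pairing retains same-genome passing pairs and tallies exclusions", {
  r <- rbind(rec("p1", 1, "phage"), rec("p1", 2, "phage"),
             rec("p2", 1, "phage"), rec("p2", 2, "host"),
             rec("p3", 1, "host"),                        # orphaned mate
             rec("p4", 1, "phage"), rec("p4", 2, "phage", mm = 20))
  ps <- pair_and_screen(r)
  expect_equal(ps$pairs$read_id, "p1")
  ex <- stats::setNames(ps$exclusions$reason, ps$exclusions$read_id)
  expect_identical(ex[["p2"]], "cross_genome")
  expect_identical(ex[["p3"]], "orphan")
  expect_identical(ex[["p4"]], "filtered")
})

test_that("pair-in-ORF counting matches a hand-counted toy fixture", {
  models <- gene_model_set(
    genome_id = "phage", gene_id = c("gp091", "gp092"),
    start = c(100L, 1000L), end = c(600L, 1400L))
  ## 3 pairs inside gp091, 1 spanning its boundary, 1 intergenic
  pairs <- data.frame(
    read_id = paste0("r", 1:5), genome_id = "phage",
    start1 = c(100L, 200L, 300L, 550L, 700L),
    end1 = c(225L, 325L, 425L, 675L, 825L),
    start2 = c(300L, 400L, 475L, 650L, 800L),
    end2 = c(425L, 525L, 600L, 775L, 925L),
    decoy = NA_character_, source_gene = NA_character_,
    stringsAsFactors = FALSE)
  cm <- count_pairs(pairs, models, containment = "both_within")
  expect_equal(unname(cm$counts["gp091", 1]), 3L)
  expect_equal(unname(cm$counts["gp092", 1]), 0L)
  expect_equal(unname(cm$intergenic[1]), 2L)
  expect_equal(unname(cm$library_size[1]), 5)
  ## conservation: genes + intergenic = retained pairs
  expect_equal(sum(cm$counts) + sum(cm$intergenic), nrow(pairs))
  ## the boundary-spanning pair is recovered by the looser rules
  cm2 <- count_pairs(pairs, models, containment = "any_overlap")
  expect_equal(unname(cm2$counts["gp091", 1]), 4L)
})

test_that("an empty SAM yields an all-zero matrix with zero library size", {
  path <- write_toy_sam(character(0))
  models <- gene_model_set("phage", c("gp001", "gp002"),
                           c(0L, 500L), c(400L, 900L))
  cm <- quantify_sam(c(s1 = path), models)
  expect_true(all(cm$counts == 0L))
  expect_equal(unname(cm$library_size), 0)
})

test_that("mismatches fall back to the MD tag when NM is absent", {
  line <- paste("r1", 99, "phage", 101, 60, "125M", "=", 300, 324,
                "*", "*", "MD:Z:10A114", sep = "\t")
  line2 <- paste("r1", 147, "phage", 300, 60, "125M", "=", 101, -324,
                 "*", "*", "MD:Z:125", sep = "\t")
  recs <- read_sam_records(write_toy_sam(c(line, line2)))
  expect_equal(recs$mismatches, c(1L, 0L))
  ## neither NM nor MD: record is rejected with a warning
  bad <- paste("r2", 99, "phage", 101, 60, "125M", "=", 300, 324,
               "*", "*", sep = "\t")
  expect_warning(out <- read_sam_records(write_toy_sam(bad)), "rejected")
  expect_equal(nrow(out), 0L)
})

test_that("synthetic fixtures round-trip exactly through quantification", {
  cfg <- small_sim_config(n_samples = 3, library_size_range = c(500, 900),
                          seq_error_rate = 0, decoy_fraction = 0, seed = 42)
  ds <- simulate_dataset(cfg)
  fx <- emit_read_fixtures(ds$counts, ds$models, cfg, tempfile("rt"))
  cm <- quantify_sam(stats::setNames(fx$path, fx$sample), ds$models)
  expect_identical(cm$counts[rownames(ds$counts$counts),
                             colnames(ds$counts$counts)],
                   ds$counts$counts)
  expect_equal(unname(cm$library_size), unname(colSums(ds$counts$counts)))
  expect_true(all(cm$intergenic == 0L))
})

test_that("tightening either filter fraction never increases any count", {
  cfg <- small_sim_config(n_samples = 2, library_size_range = c(400, 700),
                          seq_error_rate = 0.05, seed = 17)
  ds <- simulate_dataset(cfg)
  fx <- emit_read_fixtures(ds$counts, ds$models, cfg, tempfile("mono"))
  paths <- stats::setNames(fx$path, fx$sample)
  loose <- quantify_sam(paths, ds$models, min_identity_fraction = 0.9)
  tight_id <- quantify_sam(paths, ds$models, min_identity_fraction = 0.97)
  tight_len <- quantify_sam(paths, ds$models, min_length_fraction = 0.99)
  expect_true(all(tight_id$counts <= loose$counts))
  expect_true(all(tight_len$counts <= loose$counts))
  expect_true(sum(tight_id$counts) < sum(loose$counts))
})
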