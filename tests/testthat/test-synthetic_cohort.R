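test_that("implant_insertion reproduces the TPRT anatomy", {
  g <- paste(rep("ACGTG", 4), collapse = "")   # 20 bp
  out <- implant_insertion(g, 10, "ACGT", tsd_len = 0, polya_len = 0)
  expect_equal(nchar(out$seq), 24L)
  expect_equal(out$seq, paste0(substr(g, 1, 10), "ACGT", substr(g, 11, 20)))
  expect_error(implant_insertion(g, 25, "ACGT"), "out of range")
})

test_that("minus-orientation implants carry T-runs inside the left TSD boundary", {
  g <- paste(rep("AC", 15), collapse = "")     # 30 bp toy
  out <- implant_insertion(g, 10, "GGG", tsd_len = 4, polya_len = 15,
                           orientation = "-")
  # hand-built expectation: revcomp(GGG + A^15) = T^15 CCC
  expect_equal(out$seq, paste0(substr(g, 1, 14), strrep("T", 15), "CCC",
                               substr(g, 11, 30)))
  expect_equal(substr(out$seq, 15, 29), strrep("T", 15))
})

test_that("implanted TSDs are recovered exactly by refinement (round trip)", {
  for (ori in c("+", "-")) for (tsd in c(0L, 5L, 12L)) {
    tl <- toy_locus(tsd_len = tsd, polya_len = 18, orientation = ori,
                    seed = 100 + tsd)
    sv_len <- nchar(tl$filled) - nchar(tl$empty)
    r <- refine_locus(tl$filled, tl$empty, tl$site + tsd, tl$site + tsd, sv_len)
    expect_true(r$qc_pass)
    expect_equal(r$tsd_len, tsd)
    expect_equal(r$tsd_seq, tl$truth$tsd_seq)
    pa <- detect_polya(r$insert_seq, ori)
    expect_equal(pa$polya_len, 18L)
  }
})

test_that("zero rates give an SNV-only cohort and mu = 0 gives no SNVs", {
  cfg <- sim_config(tree = "(S1:2000,S2:2000);", genome_length = 1e5,
                    sine_rate = 0, line_rate = 0, seed = 3,
                    chrom_fractions = c(chr1 = 1), confounder_deletions = 0L)
  b <- simulate_cohort(cfg)
  expect_equal(nrow(b$truth), 0L)
  calls <- pair_variant_calls(b, "S1", "S2")
  expect_true(all(calls$kind == "snv"))
  expect_gt(nrow(calls), 0)

  cfg0 <- sim_config(tree = "(S1:2000,S2:2000);", genome_length = 1e5,
                     mu = 0, seed = 3, chrom_fractions = c(chr1 = 1),
                     confounder_deletions = 0L)
  b0 <- simulate_cohort(cfg0)
  calls0 <- pair_variant_calls(b0, "S1", "S2")
  snv <- extract_snvs(read_snv_table(calls0),
                      pair_homologous_regions(b0, "S1", "S2"))
  expect_equal(snv$snv_count, 0L)
})

test_that("insertion counts per branch follow the Poisson expectation", {
  # 2 samples, 2,000 generations/branch, rate 1/20 -> 100 expected per branch
  cfg <- sim_config(tree = "(S1:2000,S2:2000);", genome_length = 1e6,
                    sine_rate = 1 / 20, line_rate = 0, seed = 5,
                    chrom_fractions = c(chr1 = 1), confounder_deletions = 0L)
  b <- simulate_cohort(cfg)
  for (br in c("S1", "S2")) {
    n <- sum(b$truth$branch == br)
    expect_lt(abs(n - 100), 4 * sqrt(100))
  }
})

test_that("noise-free emitted calls hit every truth insertion exactly once", {
  b <- small_bundle()
  calls <- pair_variant_calls(b, "GSD1")
  paths <- retrodiff:::.paths(b$tree)
  sym <- c(setdiff(paths$GSD1, paths$G_WOLF), setdiff(paths$G_WOLF, paths$GSD1))
  tv <- b$truth[b$truth$branch %in% sym & !b$truth$is_het_in_assembly, ]
  sv <- calls[calls$kind != "snv" & !is.na(calls$event_id), ]
  counts <- table(sv$event_id)
  expect_true(all(tv$event_id %in% names(counts)))
  expect_true(all(counts[tv$event_id] == 1))
  # coordinates are exact: for sample-side insertions the target junction
  # equals the truth site lifted into outgroup coordinates
  qside <- tv[tv$branch %in% setdiff(paths$GSD1, paths$G_WOLF), ]
  for (i in sample(nrow(qside), min(20, nrow(qside)))) {
    ev <- qside[i, ]
    got <- sv[sv$event_id == ev$event_id, ]
    exp_pos <- lift_position(b, "G_WOLF", ev$chrom, ev$site) + ev$tsd_len
    expect_equal(got$target_start, exp_pos)
  }
})

test_that("heterozygous-assembly omission removes terminal insertions from calls", {
  cfg <- sim_config(tree = "(S1:3000,S2:3000);", genome_length = 3e5,
                    seed = 8, chrom_fractions = c(chr1 = 1),
                    het_sampling_bias = c(S1 = 0.4, S2 = 1),
                    confounder_deletions = 0L)
  b <- simulate_cohort(cfg)
  omitted <- b$truth[b$truth$is_het_in_assembly, ]
  expect_gt(nrow(omitted), 0)
  expect_true(all(omitted$branch == "S1"))
  calls <- pair_variant_calls(b, "S1", "S2")
  expect_false(any(omitted$event_id %in% calls$event_id))
  # omitted events are also absent from the emitted genome: the junction
  # 30-mer (flank + block start) exists only when the insertion is present
  ev <- omitted[1, ]
  root <- b$ancestor_genome[[ev$chrom]]
  flank <- substr(root, ev$site + ev$tsd_len - 14, ev$site + ev$tsd_len)
  probe <- paste0(flank, substr(ev$block, 1, 15))
  expect_false(grepl(probe, b$genomes$S1[[ev$chrom]], fixed = TRUE))
  kept <- b$truth[!b$truth$is_het_in_assembly & b$truth$branch == "S1", ][1, ]
  flank2 <- substr(root, kept$site + kept$tsd_len - 14, kept$site + kept$tsd_len)
  probe2 <- paste0(flank2, substr(kept$block, 1, 15))
  expect_true(grepl(probe2, b$genomes$S1[[kept$chrom]], fixed = TRUE))
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(tree = "(S1:1000,S2:1000);", genome_length = 1e5,
                    seed = 77, chrom_fractions = c(chr1 = 1))
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$genomes, b2$genomes)
  expect_identical(b1$truth, b2$truth)
})

test_that("cohort bundles round-trip to disk as plain text", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  fa <- read_fasta(file.path(dir, "GSD1.fa"))
  expect_equal(unname(fa["chr1"]), b$genomes$GSD1$chr1)
  ann <- read_repeat_annotation(file.path(dir, "GSD1.out"), "rm_out")
  expect_equal(nrow(ann), nrow(b$annotations$GSD1))
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, b$samples)
})
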