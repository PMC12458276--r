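test_that("noise-free refinement recovers the exact breakpoint and insert", {
  tl <- toy_locus(tsd_len = 12, polya_len = 20)
  sv_len <- nchar(tl$filled) - nchar(tl$empty)
  r <- refine_locus(tl$filled, tl$empty, tl$site + 12, tl$site + 12, sv_len)
  expect_true(r$qc_pass)
  expect_equal(r$refined_junction, tl$site + 12)
  expect_equal(r$insert_len, sv_len)
  expect_equal(r$non_tsd_bp, sv_len - 12L)
  expect_equal(r$insert_seq, tl$truth$block)
})

test_that("jittered calls are rescued via the reduced-flank retry", {
  tl <- toy_locus(tsd_len = 10, polya_len = 15, n = 6000, site = 3000,
                  seed = 17)
  sv_len <- nchar(tl$filled) - nchar(tl$empty)
  r <- refine_locus(tl$filled, tl$empty, tl$site + 10 + 200, tl$site + 10 + 200,
                    sv_len)
  expect_true(r$qc_pass)
  expect_equal(r$flank_used, 500L)
  expect_equal(r$refined_junction, tl$site + 10)
  expect_equal(r$tsd_len, 10L)
})

test_that("short inserts and low non-TSD content fail QC", {
  tl <- toy_locus(tsd_len = 4, polya_len = 0, el_len = 41, seed = 21)
  sv_len <- nchar(tl$filled) - nchar(tl$empty)   # 45 bp
  r <- refine_locus(tl$filled, tl$empty, tl$site + 4, tl$site + 4, sv_len)
  expect_false(r$qc_pass)
  expect_equal(r$qc_reason, "short")

  tl2 <- toy_locus(tsd_len = 25, polya_len = 0, el_len = 28, seed = 22)
  sv2 <- nchar(tl2$filled) - nchar(tl2$empty)    # 53 bp, 28 non-TSD
  r2 <- refine_locus(tl2$filled, tl2$empty, tl2$site + 25, tl2$site + 25, sv2)
  expect_false(r2$qc_pass)
  expect_equal(r2$qc_reason, "low_non_tsd")
})

test_that("target site deletions are called from the empty-side remainder", {
  g <- rand_genome(3000, 31)
  p <- substr(g, 1, 1500); s <- substr(g, 1506, 3000)
  d <- substr(g, 1501, 1505)                       # 5 bp lost at the junction
  ins <- paste0("G", rand_genome(120, 32), "C")
  filled <- paste0(p, ins, s)
  empty <- paste0(p, d, s)
  r <- refine_locus(filled, empty, 1500, 1500, nchar(ins))
  expect_true(r$qc_pass)
  expect_equal(r$ts_del_len, 5L)
  expect_equal(r$tsd_len, 0L)
  expect_equal(r$insert_seq, ins)
})

test_that("blunt insertions give empty TSD and zero target site deletion", {
  tl <- toy_locus(tsd_len = 0, polya_len = 0, seed = 35)
  sv_len <- nchar(tl$filled) - nchar(tl$empty)
  r <- refine_locus(tl$filled, tl$empty, tl$site, tl$site, sv_len)
  expect_true(r$qc_pass)
  expect_equal(r$tsd_len, 0L)
  expect_equal(r$ts_del_len, 0L)
})

test_that("refinement is translation invariant", {
  tl <- toy_locus(tsd_len = 8, polya_len = 12, seed = 40)
  sv_len <- nchar(tl$filled) - nchar(tl$empty)
  prefix <- rand_genome(500, 41)
  r0 <- refine_locus(tl$filled, tl$empty, tl$site + 8, tl$site + 8, sv_len)
  r1 <- refine_locus(paste0(prefix, tl$filled), paste0(prefix, tl$empty),
                     tl$site + 8 + 500, tl$site + 8 + 500, sv_len)
  expect_equal(r1$insert_start, r0$insert_start + 500L)
  expect_equal(r1$refined_junction, r0$refined_junction + 500L)
  expect_equal(r1$tsd_seq, r0$tsd_seq)
})

test_that("call_tsd allows mismatches only when configured", {
  tl <- toy_locus(tsd_len = 12, polya_len = 15, seed = 44)
  # degrade one base of the downstream TSD copy in the filled allele
  filled <- tl$filled
  pos <- tl$site + 12 + nchar(tl$truth$block) + 3   # inside TSD copy 2
  old <- substr(filled, pos + 1, pos + 1)
  substr(filled, pos + 1, pos + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sv_len <- nchar(filled) - nchar(tl$empty)
  r0 <- refine_locus(filled, tl$empty, tl$site + 12, tl$site + 12, sv_len)
  r1 <- refine_locus(filled, tl$empty, tl$site + 12, tl$site + 12, sv_len,
                     tsd_max_mismatch = 1L)
  expect_lt(r0$tsd_len, 12L)
  expect_equal(r1$tsd_len, 12L)
})

test_that("LINE-1 false-positive filters drop embedded loci without TSDs", {
  ann <- data.frame(chrom = "chr1", start = 1000L, end = 7000L, strand = "+",
                    repeat_class = "LINE/L1", subfamily = "L1_Cf",
                    divergence_pct = 10, stringsAsFactors = FALSE)
  refined <- data.frame(qc_pass = TRUE, qc_reason = "", flank_used = 1000L,
                        insert_start = 2000L, insert_end = 2400L,
                        refined_junction = 2000L, insert_seq = "",
                        tsd_seq = "", tsd_len = 0L, ts_del_len = 0L,
                        non_tsd_bp = 400L, insert_len = 400L,
                        stringsAsFactors = FALSE)
  out <- apply_line1_fp_filters(refined, ann, "chr1")
  expect_false(out$qc_pass)
  expect_equal(out$qc_reason, "embedded_no_tsd")
  # a true nested insertion with a 12 bp TSD is retained: its own annotation
  # covers the insert, and the TSD excuses the surrounding old element
  ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 2000L, end = 2400L,
                                strand = "+", repeat_class = "LINE/L1",
                                subfamily = "L1_Cf", divergence_pct = 0.5,
                                stringsAsFactors = FALSE))
  refined$tsd_len <- 12L
  expect_true(apply_line1_fp_filters(refined, ann2, "chr1")$qc_pass)
  # low LINE-1 content is dropped regardless
  refined$insert_end <- 2700L; refined$insert_len <- 700L
  out3 <- apply_line1_fp_filters(refined, ann2[2, ], "chr1")
  expect_false(out3$qc_pass)
  expect_equal(out3$qc_reason, "low_l1_content")
})
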