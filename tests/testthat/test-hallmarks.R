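ann_row <- function(start, end, strand = "+", class = "SINE/tRNA-Lys",
                    subfam = "SINEC2A1_Cf", chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             repeat_class = class, subfamily = subfam, divergence_pct = 1,
             stringsAsFactors = FALSE)
}

test_that("orientation voting follows the 20 bp segment rule", {
  expect_equal(detect_orientation(ann_row(100L, 280L, "-"), "chr1", 100L, 300L),
               "-")
  two <- rbind(ann_row(100L, 150L, "+"), ann_row(200L, 280L, "-"))
  expect_equal(detect_orientation(two, "chr1", 100L, 300L), "ambiguous")
  expect_equal(detect_orientation(ann_row(100L, 115L), "chr1", 100L, 300L),
               "removed")
  # a long segment overlapping the insert by only 15 bp does not vote
  expect_equal(detect_orientation(ann_row(0L, 115L), "chr1", 100L, 300L),
               "removed")
})

test_that("poly(A) detection honours the gap rule and prefers longer runs", {
  ins <- paste0(rand_genome(80, 1), strrep("A", 11))
  expect_equal(detect_polya(ins, "+"), list(polya_len = 11L, polya_gap = 0L))
  # a 13 bp run separated by 6 bases is ineligible
  ins2 <- paste0(rand_genome(60, 2), strrep("A", 13), "GCGCGC")
  expect_equal(detect_polya(ins2, "+")$polya_len, 0L)
  # of two eligible runs (15 at gap 4 and 3 at gap 0), the longer is chosen
  ins3 <- paste0(rand_genome(40, 3), strrep("A", 15), "G", strrep("A", 3))
  expect_equal(detect_polya(ins3, "+"), list(polya_len = 15L, polya_gap = 4L))
  # minus orientation reads T-runs at the 5' edge of the insert
  ins4 <- paste0(strrep("T", 14), "G", rand_genome(60, 4))
  expect_equal(detect_polya(ins4, "-"), list(polya_len = 14L, polya_gap = 0L))
  # runs below 10 bp are not reported
  expect_equal(detect_polya(paste0(rand_genome(30, 5), "AAAAAAA"), "+")$polya_len, 0L)
})

test_that("endonuclease sites are mirrored onto the minus strand", {
  # plus locus: upstream TT, TSD starting AAAAA -> revcomp(TTAAAAA) = TTTTTAA
  g <- paste0(rand_genome(50, 6), "TT", "AAAAACGCGT", rand_genome(50, 7))
  # insert begins after a 10 bp TSD starting at position 52 (0-based)
  en <- extract_en_site(g, insert_start = 62L, insert_end = 80L,
                        tsd_len = 10L, orientation = "+")
  expect_equal(en, "TTTTTAA")
  expect_true(is.na(extract_en_site(g, 62L, 80L, 8L, "+")))
  expect_true(is.na(extract_en_site(g, 62L, 80L, 12L, "ambiguous")))
  # minus locus: right TSD ends TTTTT, downstream AA, read on the plus strand
  g2 <- paste0(rand_genome(60, 8), "CGCGCTTTTT", "AA", rand_genome(40, 9))
  en2 <- extract_en_site(g2, insert_start = 30L, insert_end = 60L,
                         tsd_len = 10L, orientation = "-")
  expect_equal(en2, "TTTTTAA")
})

test_that("stringent and relaxed classification match their thresholds", {
  expect_equal(classify_hallmarks(12, 15, 2, "+"), "both")
  expect_equal(classify_hallmarks(12, 0, NA, "+"), "tsd_only")
  expect_equal(classify_hallmarks(4, 15, 0, "+"), "polya_only")
  expect_equal(classify_hallmarks(4, 0, NA, "+"), "neither")
  expect_equal(classify_hallmarks(12, 15, 2, "ambiguous"), "ambiguous")
  # tsd 8 with a degraded tail window: relaxed both, stringent neither
  ins <- paste0(rand_genome(100, 10), "AAAAAAAAAACGAAA", rand_genome(20, 11))
  expect_equal(classify_hallmarks(8, 0, NA, "+", ins, "stringent"), "neither")
  expect_equal(classify_hallmarks(8, 0, NA, "+", ins, "relaxed"), "both")
  # the window must lie within 30 bp of the junction
  far <- paste0("AAAAAAAAAACGAAA", rand_genome(60, 12))
  expect_equal(classify_hallmarks(8, 0, NA, "+", far, "relaxed"), "tsd_only")
})

test_that("relaxation is monotone: relaxed both includes every stringent both", {
  pr <- small_pair()
  l <- pr$loci[pr$loci$qc_pass, ]
  s_both <- l$stringent_class == "both"
  r_both <- l$relaxed_class == "both"
  expect_true(all(r_both[s_both]))
  expect_gte(sum(r_both), sum(s_both))
})

test_that("subfamily assignment merges SINEC_Cf/2A1 and flags conflicts", {
  expect_equal(assign_subfamily(ann_row(100L, 280L), "chr1", 100L, 300L),
               "SINEC_Cf/2A1")
  expect_equal(assign_subfamily(ann_row(100L, 280L, subfam = "SINEC_Cf"),
                                "chr1", 100L, 300L), "SINEC_Cf/2A1")
  both <- rbind(ann_row(100L, 280L, subfam = "SINEC_Cf"),
                ann_row(100L, 280L, subfam = "SINEC2A1_Cf"))
  expect_equal(assign_subfamily(both, "chr1", 100L, 300L), "SINEC_Cf/2A1")
  mixed <- rbind(ann_row(100L, 200L, class = "LINE/L1", subfam = "L1_Cf"),
                 ann_row(210L, 290L, class = "LINE/L1", subfam = "L1_Canis1"))
  expect_equal(assign_subfamily(mixed, "chr1", 100L, 300L), "unresolved")
  expect_equal(assign_subfamily(ann_row(100L, 118L), "chr1", 100L, 300L), "")
})

test_that("logo matrix counts bases per position", {
  m <- logo_matrix("TTTTTAA")
  expect_equal(dim(m), c(4L, 7L))
  expect_equal(unname(m["T", 1:5]), rep(1L, 5))
  expect_equal(unname(m["A", 6:7]), rep(1L, 2))
  expect_equal(colSums(m), rep(1L, 7), ignore_attr = TRUE)
  expect_equal(sum(logo_matrix(character(0))), 0L)
  m2 <- logo_matrix(c("TTTTTAA", "ACGTACG", NA))
  expect_equal(colSums(m2), rep(2L, 7), ignore_attr = TRUE)
})
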