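test_that("DUST masking removes homopolymers and spares random sequence", {
  polyA <- strrep("A", 40)
  expect_true(all(dust_mask(polyA)))
  expect_null(mask_low_complexity(list(seq = polyA, start = 0L, end = 40L)))
  rnd <- rand_genome(40, 61)
  expect_false(any(dust_mask(rnd)))
  mixed <- list(seq = paste0(rand_genome(30, 62), strrep("A", 30)),
                start = 0L, end = 60L)
  out <- mask_low_complexity(mixed)
  expect_equal(out$unmasked_bp, 30L)
  expect_equal(out$seq, mixed$seq)   # the original sequence is kept for search
})

test_that("candidate extraction takes the tail beyond the longest annotation", {
  g <- rand_genome(5000, 63)
  ann <- function(s, e, strand = "+")
    data.frame(chrom = "chr1", start = s, end = e, strand = strand,
               repeat_class = "LINE/L1", subfamily = "L1_Cf",
               divergence_pct = 1, stringsAsFactors = FALSE)
  # 60 bp tail beyond the annotation
  cand <- extract_transduction_candidate(g, "chr1", 1000L, 2060L, "+",
                                         ann(1000L, 2000L))
  expect_equal(nchar(cand$seq), 60L)
  expect_equal(cand$seq, substr(g, 2001, 2060))
  # an 18 bp tail is below the 25 bp minimum
  expect_null(extract_transduction_candidate(g, "chr1", 1000L, 2018L, "+",
                                             ann(1000L, 2000L)))
  # with two overlapping annotations the longest is chosen
  two <- rbind(ann(1000L, 1500L), ann(1000L, 2000L))
  cand2 <- extract_transduction_candidate(g, "chr1", 1000L, 2060L, "+", two)
  expect_equal(nchar(cand2$seq), 60L)
  # minus orientation reads the tail from the left edge, reverse complemented
  cand3 <- extract_transduction_candidate(g, "chr1", 940L, 2000L, "-",
                                          ann(1000L, 2000L))
  expect_equal(cand3$seq, revcomp(substr(g, 941, 1000)))
})

test_that("genome search finds a unique copy at its exact location", {
  set.seed(65)
  genome <- list(chr1 = rand_genome(50000, 66), chr2 = rand_genome(30000, 67))
  td <- substr(genome$chr2, 20001, 20120)
  cand <- mask_low_complexity(list(seq = td, start = 0L, end = 120L))
  hits <- search_genome(cand, genome, self_chrom = "chr1",
                        self_start = 1000L, self_end = 1001L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$chrom, "chr2")
  expect_equal(hits$start, 20000L)
  expect_equal(hits$end, 20120L)
  expect_gte(hits$identity, 0.95)
  # the reverse-complement copy is found on the minus strand
  cand_rc <- mask_low_complexity(list(seq = revcomp(td), start = 0L,
                                      end = 120L))
  hits_rc <- search_genome(cand_rc, genome, self_chrom = "chr1",
                           self_start = 1000L, self_end = 1001L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 20000L)
})

test_that("self-proximal hits are suppressed within 10 kb", {
  genome <- list(chr1 = rand_genome(40000, 68))
  td <- substr(genome$chr1, 15001, 15100)
  cand <- mask_low_complexity(list(seq = td, start = 0L, end = 100L))
  near <- search_genome(cand, genome, self_chrom = "chr1",
                        self_start = 14000L, self_end = 14001L)
  expect_equal(nrow(near), 0L)
  far <- search_genome(cand, genome, self_chrom = "chr1",
                       self_start = 30000L, self_end = 30001L)
  expect_equal(nrow(far), 1L)
})

test_that("hyper-repetitive candidates are voided beyond 50 alignments", {
  seg <- rand_genome(60, 69)
  genome <- list(chr1 = paste(rep(c(seg, rand_genome(100, 70)), 60),
                              collapse = ""))
  cand <- mask_low_complexity(list(seq = seg, start = 0L, end = 60L))
  out <- search_genome(cand, genome, self_chrom = "chr2", self_start = 0L,
                       self_end = 1L)
  expect_equal(nrow(out), 0L)
  expect_true(isTRUE(attr(out, "voided")))
})

test_that("parent adjacency requires a downstream, concordant LINE-1", {
  ann <- function(s, e, strand)
    data.frame(chrom = "chr1", start = s, end = e, strand = strand,
               repeat_class = "LINE/L1", subfamily = "L1_Cf",
               divergence_pct = 1, stringsAsFactors = FALSE)
  hit <- function(s, e, strand = "+", sample = "S1", id = "L1")
    data.frame(chrom = "chr1", start = s, end = e, strand = strand,
               identity = 1, match_bp = e - s, sample = sample,
               locus_id = id, stringsAsFactors = FALSE)
  # parent just upstream on the plus strand -> adjacent
  out <- classify_sources(hit(5030L, 5130L), ann(1000L, 5010L, "+"))
  expect_true(out$hits$parent_adjacent)
  # too far downstream
  out2 <- classify_sources(hit(5100L, 5200L), ann(1000L, 5010L, "+"))
  expect_false(out2$hits$parent_adjacent)
  # wrong orientation
  out3 <- classify_sources(hit(5030L, 5130L, strand = "-"),
                           ann(1000L, 5010L, "+"))
  expect_false(out3$hits$parent_adjacent)
  # minus-strand parent: the hit must sit on its left
  out4 <- classify_sources(hit(4870L, 4970L, strand = "-"),
                           ann(5000L, 9000L, "-"))
  expect_true(out4$hits$parent_adjacent)
  # no annotation at all ("parentless")
  out5 <- classify_sources(hit(5030L, 5130L), ann(1000L, 5010L, "+")[0, ])
  expect_false(out5$hits$parent_adjacent)
})

test_that("recurrent sources are clusters backing multiple insertions", {
  hits <- data.frame(
    chrom = "chr1", start = c(1000L, 1040L, 8000L), end = c(1100L, 1140L, 8100L),
    strand = "+", identity = 1, match_bp = 100L,
    sample = c("S1", "S2", "S1"), locus_id = c("a", "b", "c"),
    stringsAsFactors = FALSE)
  out <- classify_sources(hits, data.frame(chrom = character(),
                                           start = integer(), end = integer(),
                                           strand = character(),
                                           repeat_class = character(),
                                           subfamily = character(),
                                           divergence_pct = numeric()))
  expect_equal(nrow(out$clusters), 2L)
  expect_equal(out$clusters$recurrent, c(TRUE, FALSE))
  expect_equal(out$clusters$n_events, c(2L, 1L))
})
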