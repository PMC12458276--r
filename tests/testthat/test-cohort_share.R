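mk_loci <- function(pos, comparison, carrier = comparison,
                    direction = "query", class = "SINEC", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, carrier = carrier,
             comparison = comparison, direction = direction,
             element_class = class,
             locus_id = paste0("L", seq_along(pos)), stringsAsFactors = FALSE)
}

test_that("callable regions are the pair intersection minus exclusions", {
  cov <- list(interval_df("chr1", 0L, 10000L),
              interval_df("chr1", c(0L, 300L), c(100L, 10000L)))
  excl <- interval_df("chr1", 5000L, 5200L)
  callable <- compute_callable(cov, excl)
  expect_equal(iv_total_len(callable), 100 + (10000 - 300) - 200)
  # a locus inside the uncallable window [100,300) is dropped downstream
  expect_equal(iv_covered_bp(interval_df("chr1", 150L, 151L), callable), 0L)
  # full coverage everywhere keeps everything
  all_cov <- compute_callable(list(interval_df("chr1", 0L, 1000L)))
  expect_equal(iv_total_len(all_cov), 1000L)
})

test_that("callable computation matches a per-base oracle on a 10 kb toy", {
  set.seed(23)
  n <- 10000L
  cov <- lapply(1:3, function(i) {
    s <- sort(sample(n - 400, 10))
    interval_df("chr1", s, s + sample(400, 10))
  })
  excl <- interval_df("chr1", s2 <- sample(n - 200, 4), s2 + 200L)
  want <- Reduce(`&`, lapply(cov, brute_covered, n = n)) &
    !brute_covered(n, excl)
  expect_equal(brute_covered(n, compute_callable(cov, excl)), want)
})

test_that("locus merging follows the 100 bp single-linkage rule", {
  # same insertion called at 1000 (GSD1) and 1050 (DNG): one locus, both carry
  m <- merge_loci(mk_loci(c(1000L, 1050L), c("GSD1", "DNG")))
  expect_equal(nrow(m$merged), 1L)
  expect_equal(m$merged$carriers, "DNG,GSD1")
  # two variants 80 bp apart contributed by one comparison: cluster discarded
  m2 <- merge_loci(mk_loci(c(2000L, 2080L), c("GSD1", "GSD1")))
  expect_equal(nrow(m2$merged), 0L)
  expect_equal(m2$discarded, 1L)
  # loci 150 bp apart stay separate
  m3 <- merge_loci(mk_loci(c(3000L, 3150L), c("GSD1", "DNG")))
  expect_equal(nrow(m3$merged), 2L)
  # mixed element classes in one cluster are discarded
  m4 <- merge_loci(mk_loci(c(4000L, 4050L), c("GSD1", "DNG"),
                           class = c("SINEC", "LINE1")))
  expect_equal(m4$discarded, 1L)
})

test_that("merging is invariant to input order", {
  set.seed(31)
  loci <- mk_loci(sample(seq(1000L, 9000L, by = 400L)),
                  sample(c("GSD1", "GSD2", "DNG"), 21, replace = TRUE))
  m1 <- merge_loci(loci)
  m2 <- merge_loci(loci[sample(nrow(loci)), ])
  expect_equal(m1$merged[order(m1$merged$pos), ],
               m2$merged[order(m2$merged$pos), ], ignore_attr = TRUE)
})

test_that("deletion-direction calls imply presence in uncalled samples", {
  samples <- c("S1", "S2", "S3", "OG")
  # an outgroup-lineage variant: every comparison reports the deletion
  del <- mk_loci(rep(5000L, 3), c("S1", "S2", "S3"), carrier = "OG",
                 direction = "target")
  m <- merge_loci(del, samples = samples, outgroup = "OG")
  expect_equal(m$merged$carriers, "OG")
  # a variant shared by OG and S3: comparisons S1, S2 see the deletion, the
  # S3 comparison sees nothing (both genomes carry it)
  shared <- mk_loci(rep(6000L, 2), c("S1", "S2"), carrier = "OG",
                    direction = "target")
  m2 <- merge_loci(shared, samples = samples, outgroup = "OG")
  expect_equal(m2$merged$carriers, "OG,S3")
})

test_that("presence matrix has an all-absent ancestor and exact patterns", {
  merged <- data.frame(
    cohort_locus = c("a", "b", "c"), chrom = "chr1",
    pos = c(1L, 2L, 3L), element_class = "SINEC",
    carriers = c("S1", "S1,S2", "S1,S2,S3"), stringsAsFactors = FALSE)
  pm <- presence_matrix(merged, c("S1", "S2", "S3"))
  expect_true(all(!pm[, "ancestor"]))
  expect_equal(unname(rowSums(pm)), c(1, 2, 3))
  sp <- sharing_profile(pm)
  expect_equal(sp$singletons, 1L)
  expect_equal(sum(sp$patterns$count), nrow(pm))
})

test_that("sharing profiles match brute-force pattern enumeration", {
  set.seed(41)
  samples <- c("A", "B", "C", "D")
  m <- matrix(runif(20 * 4) < 0.4, 20, 4, dimnames = list(NULL, samples))
  m[rowSums(m) == 0, 1] <- TRUE
  merged <- data.frame(
    cohort_locus = paste0("l", 1:20), chrom = "chr1", pos = 1:20,
    element_class = "SINEC",
    carriers = apply(m, 1, function(r) paste(samples[r], collapse = ",")),
    stringsAsFactors = FALSE)
  pm <- presence_matrix(merged, samples)
  sp <- sharing_profile(pm)
  brute <- table(apply(m, 1, function(r) paste(samples[r], collapse = ",")))
  expect_equal(sort(sp$patterns$count), sort(as.integer(brute)))
  expect_equal(sp$singletons, sum(rowSums(m) == 1))
})

test_that("singleton percentages reproduce printed cohort ratios", {
  expect_equal(singleton_percent(23865, 51572), 46.3)
  expect_equal(singleton_percent(4034, 7428), 54.3)
  one_locus <- presence_matrix(
    data.frame(cohort_locus = "a", chrom = "chr1", pos = 1L,
               element_class = "SINEC", carriers = "S1,S2",
               stringsAsFactors = FALSE), c("S1", "S2"))
  expect_equal(sharing_profile(one_locus)$singletons, 0L)
})
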