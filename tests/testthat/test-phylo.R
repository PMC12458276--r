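pm_from <- function(m, samples) {
  merged <- data.frame(
    cohort_locus = paste0("l", seq_len(nrow(m))), chrom = "chr1",
    pos = seq_len(nrow(m)), element_class = "SINEC",
    carriers = apply(m, 1, function(r) paste(samples[r], collapse = ",")),
    stringsAsFactors = FALSE)
  presence_matrix(merged, samples)
}

test_that("p-distances are proportions of differing loci", {
  samples <- c("A", "B")
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
              ncol = 2, dimnames = list(NULL, samples))
  pm <- pm_from(m, samples)
  d <- p_distance_matrix(pm)
  expect_equal(d["A", "B"], mean(m[, 1] != m[, 2]))
  expect_equal(d["A", "A"], 0)
  # ancestor vs a sample with k presences of n loci is k/n
  expect_equal(d["A", "ancestor"], mean(m[, 1]))
  expect_true(isSymmetric(d))
})

test_that("rows differing at 2 of 8 loci give distance 0.25", {
  samples <- c("A", "B")
  m <- cbind(A = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
             B = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(p_distance_matrix(pm_from(m, samples))["A", "B"], 0.25)
})

test_that("3-taxon neighbor joining uses the closed-form star lengths", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.3
  d["a", "c"] <- d["c", "a"] <- 0.4
  d["b", "c"] <- d["c", "b"] <- 0.5
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(len[["b"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(len[["c"]], (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ exactly recovers additive matrices from random trees", {
  set.seed(51)
  for (ntax in 4:6) for (rep in 1:10) {
    src <- ape::rtree(ntax, br = function(n) runif(n, 0.05, 0.5))
    d <- ape::cophenetic.phylo(src)
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(src), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    # branch lengths are recovered too: path lengths match the input matrix
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("the four-point condition picks the same split as NJ on 4 taxa", {
  set.seed(57)
  for (rep in 1:20) {
    src <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.5))
    d <- ape::cophenetic.phylo(src)[c("t1", "t2", "t3", "t4"),
                                    c("t1", "t2", "t3", "t4")]
    sums <- c(t1t2 = d["t1", "t2"] + d["t3", "t4"],
              t1t3 = d["t1", "t3"] + d["t2", "t4"],
              t1t4 = d["t1", "t4"] + d["t2", "t3"])
    best <- names(which.min(sums))  # the pairing with the smallest sum
    tr <- ape::unroot(nj_tree(d))
    sister <- function(a, b) {
      p <- ape::prop.part(tr)
      any(vapply(p, function(x) setequal(tr$tip.label[x], c(a, b)) ||
                   setequal(setdiff(tr$tip.label, tr$tip.label[x]), c(a, b)),
                 logical(1)))
    }
    pairing <- switch(best, t1t2 = c("t1", "t2"), t1t3 = c("t1", "t3"),
                      t1t4 = c("t1", "t4"))
    expect_true(sister(pairing[1], pairing[2]))
  }
})

test_that("negative NJ branch lengths are clamped without losing path length", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 2, 9, 10, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are 100 for conflict-free matrices and reproducible", {
  samples <- c("A", "B", "C", "D", "E")
  blocks <- list(c(1, 2), c(4, 5), 1, 2, 3, 4, 5, c(1, 2, 3))
  m <- do.call(rbind, lapply(rep(blocks, 12), function(ix) {
    r <- rep(FALSE, 5); r[ix] <- TRUE; r
  }))
  colnames(m) <- samples
  pm <- pm_from(m, samples)
  bs <- bootstrap_support(pm, replicates = 50, seed = 4)
  expect_true(all(bs$support >= 100 - 1e-9))
  bs2 <- bootstrap_support(pm, replicates = 50, seed = 4)
  expect_identical(bs$support, bs2$support)
  expect_equal(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))
  expect_true(ape::is.rooted(bs$tree))
})

test_that("loci are assigned to the unique branch matching their carriers", {
  samples <- c("A", "B", "C", "D")
  m <- rbind(c(TRUE, FALSE, FALSE, FALSE),   # singleton A -> terminal A
             c(TRUE, TRUE, FALSE, FALSE),    # sister pair stem
             c(TRUE, FALSE, TRUE, FALSE),    # non-sister pair -> nonconforming
             c(TRUE, TRUE, TRUE, TRUE))      # all-sample branch
  m <- m[rep(1:4, 8), ]
  colnames(m) <- samples
  pm <- pm_from(m, samples)
  bs <- bootstrap_support(pm, replicates = 20, seed = 2)
  asg <- assign_loci_to_branches(pm, bs$tree)
  expect_equal(asg$total, nrow(pm))
  expect_equal(sum(asg$branch_counts) + sum(asg$nonconforming), asg$total)
  expect_equal(unname(asg$branch_counts[["A"]]), 8L)
  expect_equal(unname(asg$branch_counts[["A,B"]]), 8L)
  expect_equal(unname(asg$nonconforming[["A,C"]]), 8L)
  expect_equal(asg$fit_fraction, 0.75)
})
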