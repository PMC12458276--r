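# Shared fixtures, built in code. Expensive simulations are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

rand_genome <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a clean implanted locus on a toy genome; junction bases chosen so the
# decomposition is unambiguous
toy_locus <- function(tsd_len = 12, polya_len = 20, orientation = "+",
                      el_len = 150, site = 1500, n = 3000, seed = 42) {
  g <- rand_genome(n, seed)
  el <- paste0("G", rand_genome(el_len - 2, seed + 1), "C")
  block <- paste0(el, strrep("A", polya_len))
  if (orientation == "-") block <- revcomp(block)
  b1 <- substr(block, 1, 1); bn <- substr(block, nchar(block), nchar(block))
  # make the junction unambiguous: the base before the nick must differ from
  # the block end, the base after the TSD from the block start
  substr(g, site, site) <- setdiff(c("A", "C", "G", "T"), bn)[1]
  substr(g, site + tsd_len + 1, site + tsd_len + 1) <-
    setdiff(c("A", "C", "G", "T"), b1)[1]
  imp <- implant_insertion(g, site, el, tsd_len, polya_len, orientation)
  list(empty = g, filled = imp$seq, truth = imp$truth, element = el,
       site = site)
}

# small default-shaped cohort, cached
small_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- sim_config(genome_length = 4e5, seed = 99)
    .fixture_cache$bundle <- simulate_cohort(cfg)
  }
  .fixture_cache$bundle
}

small_pair <- function() {
  if (is.null(.fixture_cache$pair)) {
    .fixture_cache$pair <- run_pair(small_bundle(), "GSD1")
  }
  .fixture_cache$pair
}

# medium noise-free cohort + full pipeline run for the acceptance suite
acceptance_cohort <- function() {
  if (is.null(.fixture_cache$acc)) {
    cfg <- sim_config(genome_length = 1e6, tree = default_cohort_tree(0.65),
                      seed = 20251001)
    b <- simulate_cohort(cfg)
    co <- run_cohort(b, pipeline_config(bootstrap_replicates = 1000L))
    .fixture_cache$acc <- list(bundle = b, cohort = co)
  }
  .fixture_cache$acc
}

# per-base brute-force oracles for interval semantics
brute_within <- function(a_start, a_end, b, w) {
  # is any base of [a_start, a_end) within w of any interval of b (edges)?
  any(vapply(seq_len(nrow(b)), function(i) {
    gap <- max(b$start[i] - a_end, a_start - b$end[i], 0)
    gap <= w
  }, logical(1)))
}

brute_covered <- function(n, iv) {
  cov <- rep(FALSE, n)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i])
      cov[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  cov
}
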