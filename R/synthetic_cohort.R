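# Forward cohort simulator. Genomes evolve down a fixed tree (branch lengths in
# generations) from a random ancestral genome carrying aged repeat copies.
# Branch events are SNVs (Binomial(L*gens, mu)), retrotransposon insertions
# (Poisson(rate*gens)) bearing TSDs, poly(A) tails, optional 5' truncation and
# 3' transduction, and confounder deletions inside ancestral LINE-1s. Every
# stochastic draw flows from one RNG seeded from the config.

#' Synthetic element consensus sequences
#'
#' Deterministic synthetic consensi: a 200 bp tRNA-like "SINEC" with an
#' internal (CT)n tract, and a 6 kb "LINE1" with two junk-codon open reading
#' frames. Both start with G and end with C so that implanted junctions and
#' poly(A) tails are identifiable, and neither contains a homopolymer run of
#' 10 or more bases.
#'
#' @return named list with elements `SINEC` and `LINE1`.
#' @export
element_consensus <- function() {
  rng <- .lcg_stream(20240907)
  base4 <- c("A", "C", "G", "T")
  draw <- function(n) base4[rng(n) %% 4L + 1L]
  squash_runs <- function(x) {
    # cap homopolymer runs at 6
    r <- rle(x)
    long <- which(r$lengths > 6)
    if (length(long)) {
      pos <- cumsum(r$lengths)
      for (i in long) {
        idx <- (pos[i] - r$lengths[i] + 7):pos[i]
        x[idx] <- base4[(match(r$values[i], base4) %% 4) + 1L]
      }
      x <- squash_runs(x)
    }
    x
  }
  head_ <- c("G", "G", "C", "T", "A", "C", "G", "A", draw(52))
  ct <- rep(c("C", "T"), 30)
  tail_ <- draw(80)
  sinec <- squash_runs(c(head_, ct, tail_))
  stopifnot(length(sinec) == 200)
  sinec[1] <- "G"; sinec[200] <- "C"
  line1 <- squash_runs(c("G", draw(5998), "C"))
  line1[1] <- "G"; line1[6000] <- "C"
  list(SINEC = paste(sinec, collapse = ""), LINE1 = paste(line1, collapse = ""))
}

# tiny deterministic integer stream independent of the session RNG
.lcg_stream <- function(seed) {
  state <- as.double(seed)
  function(n) {
    out <- integer(n)
    for (i in seq_len(n)) {
      state <<- (1103515245 * state + 12345) %% 2147483648
      out[i] <- as.integer(state %% 1000003)
    }
    out
  }
}

#' Default study-shaped tree
#'
#' An ultrametric rooted tree over seven samples shaped like the canine
#' cohort: two sister pairs of breed dogs, a dingo outside the breed clade,
#' and a wolf pair (including the outgroup assembly) splitting basally.
#' Branch lengths are generations.
#'
#' @param scale multiplier applied to all branch lengths.
#' @return newick string.
#' @export
default_cohort_tree <- function(scale = 1) {
  t <- c(gsd = 1000, pairstem = 600, breedstem = 700, dogstem = 700,
         dng = 2300, wolf = 2600, wolfstem = 400) * scale
  sprintf("((((GSD1:%g,GSD2:%g):%g,(BOX:%g,GDN:%g):%g):%g,DNG:%g):%g,(A_WOLF:%g,G_WOLF:%g):%g);",
          t["gsd"], t["gsd"], t["pairstem"], t["gsd"], t["gsd"], t["pairstem"],
          t["breedstem"], t["dng"], t["dogstem"], t["wolf"], t["wolf"],
          t["wolfstem"])
}

#' Simulation configuration
#'
#' @param tree newick string; branch lengths are generation counts.
#' @param genome_length total ancestral genome length in bp.
#' @param chrom_fractions named fractions splitting the genome into
#'   chromosomes; chrX is excluded from autosomal analyses downstream.
#' @param mu SNV rate per bp per generation.
#' @param sine_rate,line_rate insertions per birth (per generation per lineage).
#' @param tsd_length_dist,polya_length_dist,transduction_length_dist length
#'   distribution specs (`list(kind = "uniform", min=, max=)` or
#'   `list(kind = "geometric", mean=)`).
#' @param truncation_dist LINE-1 5' truncation spec:
#'   `list(full_length_prob=, min_frac=)`; retained fraction is 1 with
#'   `full_length_prob`, else Uniform(min_frac, 1).
#' @param transduction_prob probability a LINE-1 insertion carries a 3'
#'   transduction.
#' @param transduction_parent_prob probability the transduction source sits
#'   directly downstream of an ancestral (outgroup-fixed) LINE-1.
#' @param transduction_recurrent_prob probability a transduction reuses an
#'   earlier source ("hot" parent).
#' @param en_site_bias probability an insertion site is drawn from positions
#'   matching the endonuclease motif (genomic TTAAAAA around the nick) rather
#'   than uniformly.
#' @param het_sampling_bias per-sample probability that a terminal-branch
#'   insertion is represented in the emitted haploid assembly; a named vector
#'   (missing samples default to 1) or a scalar. Values below 1 emulate
#'   assembly bias against filled heterozygous sites.
#' @param exclusion_density fraction of the ancestral genome marked as
#'   excluded regions (duplications/gaps stand-in).
#' @param confounder_deletions number of internal deletions of ancestral
#'   LINE-1s per terminal branch.
#' @param ancestral_sinec_per_mb,ancestral_line1_per_mb,ancestral_hal_per_mb
#'   density of aged ancestral repeat copies.
#' @param min_site_spacing minimum distance between insertion sites.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(tree = default_cohort_tree(),
                       genome_length = 2e6,
                       chrom_fractions = c(chr1 = 0.45, chr2 = 0.45, chrX = 0.10),
                       mu = 4.5e-9,
                       sine_rate = 1 / 20,
                       line_rate = 1 / 150,
                       tsd_length_dist = list(kind = "uniform", min = 5, max = 20),
                       polya_length_dist = list(kind = "geometric", mean = 25),
                       truncation_dist = list(full_length_prob = 0.25, min_frac = 0.02),
                       transduction_prob = 0.1,
                       transduction_parent_prob = 0.5,
                       transduction_recurrent_prob = 0.2,
                       transduction_length_dist = list(kind = "uniform", min = 50, max = 400),
                       en_site_bias = 0.5,
                       het_sampling_bias = 1.0,
                       exclusion_density = 0.02,
                       confounder_deletions = 1L,
                       ancestral_sinec_per_mb = 40,
                       ancestral_line1_per_mb = 6,
                       ancestral_hal_per_mb = 2,
                       min_site_spacing = 300L,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$transduction_prob, cfg$transduction_parent_prob,
             cfg$transduction_recurrent_prob, cfg$en_site_bias,
             unlist(cfg$het_sampling_bias), cfg$exclusion_density)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$mu < 0 || cfg$sine_rate < 0 || cfg$line_rate < 0)
    stop("rates must be >= 0")
  phy <- ape::read.tree(text = cfg$tree)
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree must have non-negative branch lengths in generations")
  cfg$phy <- phy
  structure(cfg, class = "sim_config")
}

.draw_len <- function(dist, n = 1L) {
  switch(dist$kind,
         uniform = sample(seq.int(dist$min, dist$max), n, replace = TRUE),
         geometric = stats::rgeom(n, prob = 1 / dist$mean) ,
         fixed = rep(as.integer(dist$value), n),
         stop("unknown length distribution kind: ", dist$kind))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

#' Implant one retrotransposon insertion into a sequence
#'
#' Reproduces the anatomy of target-primed reverse transcription: the
#' `tsd_len` bases following the nick are duplicated so they flank the
#' inserted block, the block is the element (plus tail) with `polya_len`
#' adenines appended, and minus-orientation blocks are reverse-complemented
#' as a whole.
#'
#' @param genome character scalar.
#' @param site 0-based nick position (number of bases before the insertion).
#' @param element_seq element body (may include transduced tail).
#' @param tsd_len target site duplication length (>= 0).
#' @param polya_len poly(A) tail length (>= 0).
#' @param orientation "+" or "-".
#' @return list with `seq` (the filled sequence) and `truth` (site, tsd_len,
#'   tsd_seq, polya_len, orientation, insert block).
#' @export
implant_insertion <- function(genome, site, element_seq, tsd_len = 0L,
                              polya_len = 0L, orientation = "+") {
  n <- nchar(genome)
  if (site < 0 || site + tsd_len > n) stop("insertion site out of range")
  block <- paste0(element_seq, strrep("A", polya_len))
  if (orientation == "-") block <- revcomp(block)
  out <- paste0(substr0(genome, 0, site + tsd_len), block,
                substr0(genome, site, n))
  list(seq = out,
       truth = list(site = site, tsd_len = as.integer(tsd_len),
                    tsd_seq = substr0(genome, site, site + tsd_len),
                    polya_len = as.integer(polya_len),
                    orientation = orientation, block = block))
}

# ---- tree helpers -----------------------------------------------------------

.node_labels <- function(phy) {
  n_tip <- length(phy$tip.label)
  lab <- c(phy$tip.label, paste0("node", seq_len(phy$Nnode) + n_tip))
  if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
    lab[(n_tip + 1):length(lab)] <- phy$node.label
  lab
}

# edges identified by child-node label; returns list leaf -> child labels on
# the root-to-leaf path
.paths <- function(phy) {
  lab <- .node_labels(phy)
  n_tip <- length(phy$tip.label)
  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  out <- lapply(seq_len(n_tip), function(i) {
    path <- character(0); node <- i
    while (node != root) { path <- c(lab[node], path); node <- parent[node] }
    path
  })
  setNames(out, phy$tip.label)
}

.edge_table <- function(phy) {
  lab <- .node_labels(phy)
  data.frame(edge = lab[phy$edge[, 2]], parent = lab[phy$edge[, 1]],
             generations = phy$edge.length,
             terminal = phy$edge[, 2] <= length(phy$tip.label),
             stringsAsFactors = FALSE)
}

# leaves under each edge (by child label)
.edge_leaves <- function(phy) {
  lab <- .node_labels(phy)
  n_tip <- length(phy$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(lab[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  out <- list()
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2]
    out[[lab[child]]] <- desc(child)
  }
  out
}

# ---- main simulator ---------------------------------------------------------

#' Simulate a genome cohort with full ground truth
#'
#' @param config a [sim_config()] object.
#' @return object of class `cohort_bundle`: per-sample genomes (named lists of
#'   chromosome strings), repeat annotations, exclusion regions, the ancestral
#'   genome, the truth table of implanted insertions, confounder deletions,
#'   the event log, and the tree.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phy <- config$phy
  samples <- phy$tip.label
  edges <- .edge_table(phy)
  paths <- .paths(phy)
  leaves_under <- .edge_leaves(phy)
  consensus <- element_consensus()

  chrom_len <- round(config$genome_length * config$chrom_fractions /
                       sum(config$chrom_fractions))
  chroms <- names(chrom_len)

  root <- lapply(chrom_len, .rand_dna)

  # ancestral repeat copies: overwrite root segments, record annotations
  anc <- .place_ancestral(root, chrom_len, consensus, config)
  root <- anc$root
  anc_ann <- anc$ann

  exclusions <- .draw_exclusions(chrom_len, config$exclusion_density)

  # per-chrom motif site lists for endonuclease-biased site choice
  plus_motif <- lapply(root, function(g)
    as.integer(gregexpr("TTAAAAA", g, fixed = TRUE)[[1]]) + 1L)   # 0-based nick
  minus_motif <- lapply(root, function(g)
    as.integer(gregexpr("TTTTTAA", g, fixed = TRUE)[[1]]) + 4L)   # 0-based end of TSD

  occupied <- lapply(chroms, function(ch) integer(0))
  names(occupied) <- chroms

  # confounder deletions: internal chunks of long ancestral LINE-1s
  conf <- .draw_confounders(anc_ann, edges, config, occupied)
  occupied <- conf$occupied
  confounders <- conf$events

  ins <- .draw_insertions(root, chrom_len, edges, config, consensus, anc_ann,
                          exclusions, plus_motif, minus_motif, occupied,
                          confounders)
  insertions <- ins$events

  snvs <- .draw_snvs(root, chrom_len, edges, config, confounders)

  # heterozygous-assembly omission on terminal branches
  bias <- config$het_sampling_bias
  if (is.null(names(bias))) bias <- setNames(rep(bias[1], length(samples)), samples)
  omit_p <- 1 - ifelse(is.na(bias[samples]), 1, bias[samples])
  names(omit_p) <- samples
  if (nrow(insertions)) {
    insertions$is_het_in_assembly <- FALSE
    term <- insertions$branch %in% samples
    if (any(term)) {
      p <- omit_p[insertions$branch[term]]
      insertions$is_het_in_assembly[term] <- stats::runif(sum(term)) < p
    }
  }

  events <- .event_log(insertions, confounders, snvs)

  genomes <- list(); annotations <- list(); excl_by_sample <- list()
  for (s in samples) {
    built <- .build_leaf(s, root, chrom_len, paths[[s]], events, anc_ann,
                         exclusions, insertions)
    genomes[[s]] <- built$genome
    annotations[[s]] <- built$ann
    excl_by_sample[[s]] <- built$excl
  }

  truth <- .truth_table(insertions, leaves_under)

  structure(list(samples = samples, outgroup = config$outgroup %||% "G_WOLF",
                 chrom_lengths = chrom_len, genomes = genomes,
                 ancestor_genome = root, annotations = annotations,
                 ancestral_annotation = anc_ann, exclusions = excl_by_sample,
                 ancestral_exclusions = exclusions, truth = truth,
                 confounders = confounders, events = events, tree = phy,
                 config = config),
            class = "cohort_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", length(x$samples), "samples,",
      sum(x$chrom_lengths), "bp ancestral genome\n")
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  cat("  implanted insertions:", nrow(x$truth),
      sprintf("(%d SINEC, %d LINE1)", sum(x$truth$element_class == "SINEC"),
              sum(x$truth$element_class == "LINE1")), "\n")
  cat("  confounder deletions:", nrow(x$confounders), "\n")
  invisible(x)
}

.place_ancestral <- function(root, chrom_len, consensus, config) {
  ann <- list(); k <- 0
  for (ch in names(root)) {
    L <- chrom_len[[ch]]
    mb <- L / 1e6
    n_sine <- max(0, round(config$ancestral_sinec_per_mb * mb))
    n_line <- max(0, round(config$ancestral_line1_per_mb * mb))
    n_hal <- max(0, round(config$ancestral_hal_per_mb * mb))
    spec <- rbind(
      if (n_sine > 0) data.frame(
        class = "SINE/tRNA-Lys",
        subfamily = sample(c("SINEC_Cf", "SINEC2A1_Cf"), n_sine, replace = TRUE),
        len = 200L, stringsAsFactors = FALSE),
      if (n_line > 0) data.frame(
        class = "LINE/L1", subfamily = "L1_Cf",
        len = pmax(300L, as.integer(round(stats::runif(n_line, 1500, 6000)))),
        stringsAsFactors = FALSE),
      if (n_hal > 0) data.frame(
        class = "LINE/L1", subfamily = "HAL1", len = 400L,
        stringsAsFactors = FALSE)[rep(1, n_hal), ])
    if (is.null(spec) || nrow(spec) == 0) next
    taken <- IRanges::IRanges()
    g <- root[[ch]]
    rows <- list()
    for (i in seq_len(nrow(spec))) {
      len <- spec$len[i]
      for (try in 1:50) {
        st <- sample.int(L - len - 4000L, 1) + 2000L   # keep off contig edges
        cand <- IRanges::IRanges(st + 1L, st + len)
        if (length(taken) == 0 ||
            !any(IRanges::overlapsAny(cand + 400L, taken))) break
        st <- NA
      }
      if (is.na(st)) next
      taken <- c(taken, cand)
      strand <- sample(c("+", "-"), 1)
      src <- if (spec$class[i] == "SINE/tRNA-Lys") consensus$SINEC else consensus$LINE1
      body <- substr(src, 1, min(len, nchar(src)))
      if (nchar(body) < len) body <- paste0(body, .rand_dna(len - nchar(body)))
      body <- .mutate_seq(body, stats::runif(1, 0.05, 0.15))
      if (strand == "-") body <- revcomp(body)
      substr(g, st + 1L, st + len) <- body
      k <- k + 1
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = st, end = st + len, strand = strand,
        repeat_class = spec$class[i], subfamily = spec$subfamily[i],
        divergence_pct = 10, stringsAsFactors = FALSE)
    }
    root[[ch]] <- g
    ann[[ch]] <- do.call(rbind, rows)
  }
  ann <- do.call(rbind, ann)
  if (is.null(ann)) ann <- .empty_annotation()
  rownames(ann) <- NULL
  list(root = root, ann = ann[order(ann$chrom, ann$start), , drop = FALSE])
}

.draw_exclusions <- function(chrom_len, density) {
  rows <- list()
  for (ch in names(chrom_len)) {
    L <- chrom_len[[ch]]
    target <- density * L
    tot <- 0
    while (tot < target) {
      w <- as.integer(stats::runif(1, 500, 5000))
      st <- sample.int(max(1L, L - w), 1)
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = st,
                                             end = st + w, stringsAsFactors = FALSE)
      tot <- tot + w
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(interval_df())
  iv_merge(df)
}

.draw_confounders <- function(anc_ann, edges, config, occupied) {
  rows <- list()
  l1 <- anc_ann[anc_ann$subfamily == "L1_Cf" &
                  (anc_ann$end - anc_ann$start) >= 1500, , drop = FALSE]
  term_edges <- edges$edge[edges$terminal]
  eid <- 0
  for (e in term_edges) {
    n <- config$confounder_deletions
    if (n <= 0 || nrow(l1) == 0) next
    picks <- sample.int(nrow(l1), min(n, nrow(l1)))
    for (i in picks) {
      len <- as.integer(stats::runif(1, 150, 800))
      maxoff <- (l1$end[i] - l1$start[i]) - len - 100L
      if (maxoff <= 100L) next
      off <- sample.int(maxoff - 100L, 1) + 100L
      d1 <- l1$start[i] + off
      eid <- eid + 1
      rows[[length(rows) + 1]] <- data.frame(
        event_id = sprintf("del%03d", eid), branch = e, chrom = l1$chrom[i],
        start = d1, end = d1 + len, stringsAsFactors = FALSE)
      occupied[[l1$chrom[i]]] <- c(occupied[[l1$chrom[i]]], d1, d1 + len)
    }
    l1 <- l1[-picks, , drop = FALSE]
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    ev <- data.frame(event_id = character(), branch = character(),
                     chrom = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  list(events = ev, occupied = occupied)
}

.draw_insertions <- function(root, chrom_len, edges, config, consensus,
                             anc_ann, exclusions, plus_motif, minus_motif,
                             occupied, confounders) {
  chroms <- names(chrom_len)
  chrom_p <- unlist(chrom_len) / sum(unlist(chrom_len))
  rows <- list()
  td_pool <- list()   # previously used transduction sources
  eid <- 0
  margin <- 1500L
  spacing <- config$min_site_spacing
  for (k in seq_len(nrow(edges))) {
    e <- edges$edge[k]; gens <- edges$generations[k]
    n_sine <- stats::rpois(1, config$sine_rate * gens)
    n_line <- stats::rpois(1, config$line_rate * gens)
    classes <- c(rep("SINEC", n_sine), rep("LINE1", n_line))
    for (cls in classes) {
      tsd_len <- as.integer(.draw_len(config$tsd_length_dist))
      polya_len <- as.integer(max(0, .draw_len(config$polya_length_dist)))
      orientation <- sample(c("+", "-"), 1)
      trunc_frac <- 0
      td_len <- 0L; td_src <- NULL; td_seq <- ""
      if (cls == "SINEC") {
        body <- .mutate_seq(consensus$SINEC, 0.01)
        substr(body, nchar(body), nchar(body)) <- "C"  # 3' end stays non-A
        subfam <- sample(c("SINEC_Cf", "SINEC2A1_Cf"), 1)
      } else {
        subfam <- "L1_Cf"
        if (stats::runif(1) > config$truncation_dist$full_length_prob) {
          keep <- stats::runif(1, config$truncation_dist$min_frac, 1)
          trunc_frac <- 1 - keep
        }
        full <- .mutate_seq(consensus$LINE1, 0.005)
        keep_bp <- max(60L, as.integer(round((1 - trunc_frac) * nchar(full))))
        body <- substring(full, nchar(full) - keep_bp + 1L)
        substr(body, nchar(body), nchar(body)) <- "C"  # 3' end stays non-A
        if (stats::runif(1) < config$transduction_prob) {
          src <- .pick_td_source(root, chrom_len, anc_ann, exclusions,
                                 config, td_pool)
          td_pool <- src$pool
          td_src <- src$src
          td_len <- td_src$end - td_src$start
          td_seq <- substr0(root[[td_src$chrom]], td_src$start, td_src$end)
          body <- paste0(body, td_seq)
        }
      }
      el_len <- nchar(body) - td_len
      block <- paste0(body, strrep("A", polya_len))
      if (orientation == "-") block <- revcomp(block)
      first_b <- substr(block, 1, 1); last_b <- substr(block, nchar(block), nchar(block))
      # site choice: endonuclease-motif biased with prob en_site_bias
      site <- NA; ch <- NA; motif <- FALSE
      for (try in 1:400) {
        use_motif <- stats::runif(1) < config$en_site_bias
        if (use_motif) {
          ch <- sample(chroms, 1, prob = chrom_p)
          ms <- if (orientation == "+") plus_motif[[ch]] else minus_motif[[ch]] - tsd_len
          ms <- ms[ms > margin & ms < chrom_len[[ch]] - margin]
          if (length(ms) == 0) next
          s <- ms[sample.int(length(ms), 1)]
        } else {
          ch <- sample(chroms, 1, prob = chrom_p)
          s <- sample.int(chrom_len[[ch]] - 2L * margin, 1) + margin
        }
        occ <- occupied[[ch]]
        if (length(occ) && min(abs(occ - s)) < spacing) next
        cdel <- confounders[confounders$chrom == ch, , drop = FALSE]
        if (nrow(cdel) && any(s > cdel$start - spacing & s < cdel$end + spacing))
          next
        g <- root[[ch]]
        # identifiable junction: flanking bases must not extend the duplication
        if (substr0(g, s + tsd_len, s + tsd_len + 1L) == first_b) next
        if (s > 0 && substr0(g, s - 1L, s) == last_b) next
        tsd_chars <- unique(strsplit(substr0(g, s, s + tsd_len), "", fixed = TRUE)[[1]])
        if (length(tsd_chars) == 1 &&
            (substr0(g, s - 1L, s) == tsd_chars ||
               substr0(g, s + tsd_len, s + tsd_len + 1L) == tsd_chars)) next
        site <- s; motif <- use_motif
        break
      }
      if (is.na(site)) next
      occupied[[ch]] <- c(occupied[[ch]], site)
      eid <- eid + 1
      rows[[length(rows) + 1]] <- data.frame(
        event_id = sprintf("ins%05d", eid), branch = e, element_class = cls,
        subfamily = subfam, chrom = ch, site = site, tsd_len = tsd_len,
        tsd_seq = substr0(root[[ch]], site, site + tsd_len),
        polya_len = polya_len, orientation = orientation,
        truncation_fraction = trunc_frac, el_len = el_len, td_len = td_len,
        td_chrom = if (is.null(td_src)) NA_character_ else td_src$chrom,
        td_start = if (is.null(td_src)) NA_integer_ else td_src$start,
        td_end = if (is.null(td_src)) NA_integer_ else td_src$end,
        td_parent = if (is.null(td_src)) NA else td_src$parent,
        block = block, motif_site = motif, stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) {
    ev <- data.frame(event_id = character(), branch = character(),
                     element_class = character(), subfamily = character(),
                     chrom = character(), site = integer(), tsd_len = integer(),
                     tsd_seq = character(), polya_len = integer(),
                     orientation = character(), truncation_fraction = numeric(),
                     el_len = integer(), td_len = integer(),
                     td_chrom = character(), td_start = integer(),
                     td_end = integer(), td_parent = logical(),
                     block = character(), motif_site = logical(),
                     is_het_in_assembly = logical(), stringsAsFactors = FALSE)
  }
  list(events = ev, occupied = occupied)
}

.pick_td_source <- function(root, chrom_len, anc_ann, exclusions, config, pool) {
  if (length(pool) > 0 && stats::runif(1) < config$transduction_recurrent_prob) {
    i <- sample.int(length(pool), 1)
    return(list(src = pool[[i]], pool = pool))
  }
  len <- as.integer(.draw_len(config$transduction_length_dist))
  parents <- anc_ann[anc_ann$subfamily == "L1_Cf" & anc_ann$strand == "+", ,
                     drop = FALSE]
  for (try in 1:100) {
    use_parent <- nrow(parents) > 0 &&
      stats::runif(1) < config$transduction_parent_prob
    if (use_parent) {
      i <- sample.int(nrow(parents), 1)
      ch <- parents$chrom[i]
      st <- parents$end[i] + sample.int(10L, 1) - 1L
    } else {
      ch <- sample(names(chrom_len), 1)
      st <- sample.int(chrom_len[[ch]] - len - 4000L, 1) + 2000L
    }
    if (st + len + 100L > chrom_len[[ch]]) next
    iv <- interval_df(ch, st, st + len)
    if (any(iv_covered_bp(iv, exclusions) > 0)) next
    if (!use_parent && any(iv_covered_bp(iv, anc_ann) > 0)) next
    seq <- substr0(root[[ch]], st, st + len)
    if (substr(seq, len, len) == "A") next   # keep poly(A) length identifiable
    src <- list(chrom = ch, start = st, end = st + len, parent = use_parent)
    return(list(src = src, pool = c(pool, list(src))))
  }
  # fall back to a random clean spot
  ch <- names(chrom_len)[1]
  st <- 2000L
  src <- list(chrom = ch, start = st, end = st + len, parent = FALSE)
  list(src = src, pool = c(pool, list(src)))
}

.draw_snvs <- function(root, chrom_len, edges, config, confounders) {
  rows <- list()
  for (ch in names(chrom_len)) {
    L <- chrom_len[[ch]]
    counts <- stats::rbinom(nrow(edges), L, pmin(1, config$mu * edges$generations))
    tot <- sum(counts)
    if (tot == 0) next
    pos <- sample.int(L, min(tot, L))   # distinct cohort-wide
    del <- confounders[confounders$chrom == ch, , drop = FALSE]
    if (nrow(del)) {
      bad <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(del)))
        bad <- bad | (pos > del$start[i] & pos <= del$end[i])
      pos <- pos[!bad]
    }
    counts <- pmin(counts, .redistribute(length(pos), counts))
    idx <- 0
    for (k in seq_len(nrow(edges))) {
      nk <- counts[k]
      if (nk == 0) next
      p <- pos[(idx + 1):(idx + nk)]; idx <- idx + nk
      refs <- substring(root[[ch]], p, p)
      alts <- vapply(refs, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      rows[[length(rows) + 1]] <- data.frame(
        branch = edges$edge[k], chrom = ch, pos = p - 1L, ref = refs,
        alt = alts, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(branch = character(), chrom = character(), pos = integer(),
                     ref = character(), alt = character(), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.redistribute <- function(avail, counts) {
  # trim counts so their sum fits the available distinct positions
  while (sum(counts) > avail) {
    i <- which.max(counts)
    counts[i] <- counts[i] - (sum(counts) - avail)
    counts[i] <- max(0L, counts[i])
  }
  counts
}

.event_log <- function(insertions, confounders, snvs) {
  list(insertions = insertions, deletions = confounders, snvs = snvs)
}

# shift table for a path: insertion at site s adds tsd+|block| for p >= s;
# deletion [d1,d2) subtracts its length for p >= d2
.path_shifts <- function(path, events, ch) {
  ins <- events$insertions
  ins <- ins[ins$branch %in% path & ins$chrom == ch &
               !ins$is_het_in_assembly, , drop = FALSE]
  del <- events$deletions
  del <- del[del$branch %in% path & del$chrom == ch, , drop = FALSE]
  sh <- rbind(
    if (nrow(ins)) data.frame(pos = ins$site,
                              delta = ins$tsd_len + nchar(ins$block),
                              kind = "ins", end = ins$site,
                              id = ins$event_id, stringsAsFactors = FALSE),
    if (nrow(del)) data.frame(pos = del$start, delta = -(del$end - del$start),
                              kind = "del", end = del$end, id = del$event_id,
                              stringsAsFactors = FALSE))
  if (is.null(sh))
    sh <- data.frame(pos = integer(), delta = integer(), kind = character(),
                     end = integer(), id = character(), stringsAsFactors = FALSE)
  sh[order(sh$pos), , drop = FALSE]
}

#' Project ancestral coordinates into a sample genome
#'
#' @param bundle cohort bundle.
#' @param sample sample name (or "ancestor").
#' @param chrom chromosome.
#' @param pos vector of 0-based ancestral positions.
#' @return projected 0-based positions in the sample genome.
#' @export
lift_position <- function(bundle, sample, chrom, pos) {
  if (sample == "ancestor") return(pos)
  path <- .paths(bundle$tree)[[sample]]
  sh <- .path_shifts(path, bundle$events, chrom)
  .lift_with(sh, pos)
}

.lift_with <- function(sh, pos) {
  if (nrow(sh) == 0) return(pos)
  cum <- cumsum(sh$delta)
  idx <- findInterval(pos, sh$pos + ifelse(sh$kind == "del", 1e-9, -1e-9))
  # for deletions, positions inside [d1,d2) collapse onto d1
  out <- pos + ifelse(idx > 0, cum[idx], 0)
  for (i in which(sh$kind == "del")) {
    inside <- pos >= sh$pos[i] & pos < sh$end[i]
    if (any(inside)) {
      base <- sh$pos[i] + (if (i > 1) cum[i - 1] else 0)
      out[inside] <- base
    }
  }
  out
}

.build_leaf <- function(sample, root, chrom_len, path, events, anc_ann,
                        exclusions, insertions) {
  genome <- list(); ann_rows <- list(); excl_rows <- list()
  snvs <- events$snvs
  for (ch in names(root)) {
    raw <- charToRaw(root[[ch]])
    sv <- snvs[snvs$branch %in% path & snvs$chrom == ch, , drop = FALSE]
    if (nrow(sv)) raw[sv$pos + 1L] <- charToRaw(paste(sv$alt, collapse = ""))
    sh <- .path_shifts(path, events, ch)
    pieces <- list(); prev <- 0L; offset <- 0L
    ins_here <- events$insertions[match(sh$id[sh$kind == "ins"],
                                        events$insertions$event_id), , drop = FALSE]
    ii <- 0
    for (r in seq_len(nrow(sh))) {
      if (sh$kind[r] == "ins") {
        ii <- ii + 1
        ev <- ins_here[ii, ]
        upto <- ev$site + ev$tsd_len
        pieces[[length(pieces) + 1]] <- raw[(prev + 1L):upto]
        pieces[[length(pieces) + 1]] <- charToRaw(ev$block)
        # annotation inside the inserted block: the element body, plus the
        # contiguous poly(A) tail when no transduced sequence intervenes
        # (repeat annotation of a consensus with an A-rich tail covers both)
        o_start <- ev$site + ev$tsd_len + offset
        blk <- nchar(ev$block)
        if (ev$td_len == 0) {
          el_iv <- c(o_start, o_start + blk)
        } else if (ev$orientation == "+") {
          el_iv <- c(o_start, o_start + ev$el_len)
        } else {
          el_iv <- c(o_start + blk - ev$el_len, o_start + blk)
        }
        ann_rows[[length(ann_rows) + 1]] <- data.frame(
          chrom = ch, start = el_iv[1], end = el_iv[2],
          strand = ev$orientation,
          repeat_class = if (ev$element_class == "SINEC") "SINE/tRNA-Lys" else "LINE/L1",
          subfamily = ev$subfamily, divergence_pct = 0.5,
          stringsAsFactors = FALSE)
        prev <- ev$site
        offset <- offset + ev$tsd_len + blk
      } else {
        pieces[[length(pieces) + 1]] <- raw[(prev + 1L):sh$pos[r]]
        prev <- sh$end[r]
        offset <- offset + sh$delta[r]
      }
    }
    pieces[[length(pieces) + 1]] <- raw[(prev + 1L):length(raw)]
    genome[[ch]] <- rawToChar(do.call(c, pieces))
    # lift ancestral annotations and exclusions through the events
    aa <- anc_ann[anc_ann$chrom == ch, , drop = FALSE]
    if (nrow(aa)) {
      lifted <- .lift_intervals(aa, sh)
      if (nrow(lifted)) ann_rows[[length(ann_rows) + 1]] <- lifted
    }
    ee <- exclusions[exclusions$chrom == ch, , drop = FALSE]
    if (nrow(ee)) {
      lifted <- .lift_intervals(ee, sh)
      if (nrow(lifted)) excl_rows[[length(excl_rows) + 1]] <- lifted
    }
  }
  ann <- do.call(rbind, ann_rows)
  if (is.null(ann)) ann <- .empty_annotation()
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  excl <- do.call(rbind, excl_rows)
  if (is.null(excl)) excl <- interval_df()
  rownames(excl) <- NULL
  list(genome = genome, ann = ann, excl = excl)
}

# lift a table of ancestral intervals through a path's shifts; intervals are
# split at interior insertion sites and trimmed by deletions
.lift_intervals <- function(df, sh) {
  if (nrow(sh) == 0) return(df)
  out <- list()
  cuts <- sh$pos[sh$kind == "ins"]
  dels <- sh[sh$kind == "del", , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    segs <- c(df$start[i],
              sort(cuts[cuts > df$start[i] & cuts < df$end[i]]), df$end[i])
    for (k in seq_len(length(segs) - 1)) {
      x <- segs[k]; y <- segs[k + 1]
      # subtract deletions
      pieces <- data.frame(x = x, y = y)
      for (d in seq_len(nrow(dels))) {
        new <- list()
        for (p in seq_len(nrow(pieces))) {
          px <- pieces$x[p]; py <- pieces$y[p]
          if (dels$pos[d] >= py || dels$end[d] <= px) {
            new[[length(new) + 1]] <- c(px, py)
          } else {
            if (px < dels$pos[d]) new[[length(new) + 1]] <- c(px, dels$pos[d])
            if (py > dels$end[d]) new[[length(new) + 1]] <- c(dels$end[d], py)
          }
        }
        pieces <- if (length(new)) as.data.frame(do.call(rbind, new)) else
          data.frame(x = numeric(0), y = numeric(0))
        if (nrow(pieces)) names(pieces) <- c("x", "y")
      }
      for (p in seq_len(nrow(pieces))) {
        px <- pieces$x[p]; py <- pieces$y[p]
        if (py - px < 1) next
        lx <- .lift_with(sh, px)
        row <- df[i, , drop = FALSE]
        row$start <- as.integer(lx); row$end <- as.integer(lx + (py - px))
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- df[0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.truth_table <- function(insertions, leaves_under) {
  if (nrow(insertions) == 0) {
    insertions$sample_set <- character(0)
    return(insertions)
  }
  carriers <- vapply(seq_len(nrow(insertions)), function(i) {
    set <- leaves_under[[insertions$branch[i]]]
    if (insertions$is_het_in_assembly[i]) set <- setdiff(set, insertions$branch[i])
    paste(sort(set), collapse = ",")
  }, "")
  insertions$sample_set <- carriers
  insertions
}

#' Emit pairwise variant calls from a cohort bundle
#'
#' Generates the paftools-style call set that a pairwise whole-genome
#' alignment of the two samples would produce: SNVs, insertion calls for
#' events on the query's lineage, and deletion calls for events on the
#' target's lineage (plus confounder deletions, which surface as
#' insertion/deletion calls in the opposite genome). With `jitter = 0` the
#' coordinates are exact.
#'
#' @param bundle cohort bundle.
#' @param query,target sample names; default all non-outgroup samples vs the
#'   outgroup.
#' @param jitter maximum absolute breakpoint jitter in bp applied to SV calls.
#' @return data.frame in the paftools_tsv schema with extra columns
#'   `event_id` and `len`.
#' @export
pair_variant_calls <- function(bundle, query, target = bundle$outgroup,
                               jitter = 0L) {
  paths <- .paths(bundle$tree)
  pq <- paths[[query]]; pt <- paths[[target]]
  qonly <- setdiff(pq, pt); tonly <- setdiff(pt, pq)
  ins <- bundle$events$insertions
  del <- bundle$events$deletions
  snv <- bundle$events$snvs
  rows <- list()
  add_sv <- function(ev, side) {
    ch <- ev$chrom
    shq <- .path_shifts(pq, bundle$events, ch)
    sht <- .path_shifts(pt, bundle$events, ch)
    # the event itself must not shift its own coordinates
    shq <- shq[shq$id != ev$event_id, , drop = FALSE]
    sht <- sht[sht$id != ev$event_id, , drop = FALSE]
    jit <- if (jitter > 0) sample(seq(-jitter, jitter), 1) else 0L
    blk <- nchar(ev$block); t <- ev$tsd_len
    seq_full <- paste0(ev$block, ev$tsd_seq)   # block + downstream TSD copy
    if (side == "query") {
      t0 <- .lift_with(sht, ev$site) + t + jit
      q0 <- .lift_with(shq, ev$site) + t + jit
      data.frame(target_chrom = ch, target_start = t0, target_end = t0,
                 query_chrom = ch, query_start = q0, query_end = q0 + blk + t,
                 kind = "insertion", seq = seq_full, event_id = ev$event_id,
                 stringsAsFactors = FALSE)
    } else {
      t0 <- .lift_with(sht, ev$site) + t + jit
      q0 <- .lift_with(shq, ev$site) + t + jit
      data.frame(target_chrom = ch, target_start = t0, target_end = t0 + blk + t,
                 query_chrom = ch, query_start = q0, query_end = q0,
                 kind = "deletion", seq = seq_full, event_id = ev$event_id,
                 stringsAsFactors = FALSE)
    }
  }
  iq <- ins[ins$branch %in% qonly & !ins$is_het_in_assembly, , drop = FALSE]
  it <- ins[ins$branch %in% tonly & !ins$is_het_in_assembly, , drop = FALSE]
  for (i in seq_len(nrow(iq))) rows[[length(rows) + 1]] <- add_sv(iq[i, ], "query")
  for (i in seq_len(nrow(it))) rows[[length(rows) + 1]] <- add_sv(it[i, ], "target")
  # confounder deletions
  dq <- del[del$branch %in% qonly, , drop = FALSE]
  dt <- del[del$branch %in% tonly, , drop = FALSE]
  for (i in seq_len(nrow(dq))) {
    ev <- dq[i, ]; ch <- ev$chrom
    sht <- .path_shifts(pt, bundle$events, ch)
    shq <- .path_shifts(pq, bundle$events, ch)
    t0 <- .lift_with(sht, ev$start); q0 <- .lift_with(shq, ev$start)
    rows[[length(rows) + 1]] <- data.frame(
      target_chrom = ch, target_start = t0, target_end = t0 + (ev$end - ev$start),
      query_chrom = ch, query_start = q0, query_end = q0, kind = "deletion",
      seq = substr0(bundle$ancestor_genome[[ch]], ev$start, ev$end),
      event_id = ev$event_id, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(dt))) {
    ev <- dt[i, ]; ch <- ev$chrom
    sht <- .path_shifts(pt, bundle$events, ch)
    shq <- .path_shifts(pq, bundle$events, ch)
    t0 <- .lift_with(sht, ev$start); q0 <- .lift_with(shq, ev$start)
    rows[[length(rows) + 1]] <- data.frame(
      target_chrom = ch, target_start = t0, target_end = t0,
      query_chrom = ch, query_start = q0, query_end = q0 + (ev$end - ev$start),
      kind = "insertion",
      seq = substr0(bundle$ancestor_genome[[ch]], ev$start, ev$end),
      event_id = ev$event_id, stringsAsFactors = FALSE)
  }
  # SNVs
  sq <- snv[snv$branch %in% qonly, , drop = FALSE]
  st_ <- snv[snv$branch %in% tonly, , drop = FALSE]
  snv_row <- function(ev, side) {
    ch <- ev$chrom
    sht <- .path_shifts(pt, bundle$events, ch)
    shq <- .path_shifts(pq, bundle$events, ch)
    t0 <- .lift_with(sht, ev$pos); q0 <- .lift_with(shq, ev$pos)
    if (side == "query") { ref <- ev$ref; alt <- ev$alt } else { ref <- ev$alt; alt <- ev$ref }
    data.frame(target_chrom = ch, target_start = t0, target_end = t0 + 1L,
               query_chrom = ch, query_start = q0, query_end = q0 + 1L,
               kind = "snv", seq = paste0(ref, ">", alt), event_id = NA_character_,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sq))) rows[[length(rows) + 1]] <- snv_row(sq[i, ], "query")
  for (i in seq_len(nrow(st_))) rows[[length(rows) + 1]] <- snv_row(st_[i, ], "target")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(target_chrom = character(), target_start = integer(),
                      target_end = integer(), query_chrom = character(),
                      query_start = integer(), query_end = integer(),
                      kind = character(), seq = character(),
                      event_id = character(), stringsAsFactors = FALSE)
  out$len <- ifelse(out$kind == "snv", 1L, nchar(out$seq))
  rownames(out) <- NULL
  out
}

#' Aligned-region table for a pair (full chromosome coverage)
#'
#' The simulator's pairwise alignments cover every chromosome end to end with
#' a single contig, so the aligned single-coverage regions are the full
#' chromosome extents of the target genome.
#'
#' @param bundle cohort bundle.
#' @param target target sample name.
#' @return interval table in target coordinates.
#' @export
pair_aligned_regions <- function(bundle, target = bundle$outgroup) {
  g <- bundle$genomes[[target]]
  interval_df(chrom = names(g), start = 0L,
              end = vapply(g, nchar, 1L, USE.NAMES = FALSE))
}

#' Homologous (SNV-informative) regions of a pair in target coordinates
#'
#' The target extent minus the dimorphic blocks distinguishing the pair:
#' target-lineage insertion blocks and the target-side images of
#' query-lineage deletions. SNVs can only accrue on these bases, so using
#' this footprint as the aligned length keeps the divergence estimator
#' unbiased at small genome sizes.
#'
#' @param bundle cohort bundle.
#' @param query,target sample names.
#' @return interval table in target coordinates.
#' @export
pair_homologous_regions <- function(bundle, query, target = bundle$outgroup) {
  paths <- .paths(bundle$tree)
  pq <- paths[[query]]; pt <- paths[[target]]
  tonly <- setdiff(pt, pq); qonly <- setdiff(pq, pt)
  full <- pair_aligned_regions(bundle, target)
  blocks <- list()
  ins <- bundle$events$insertions
  it <- ins[ins$branch %in% tonly & !ins$is_het_in_assembly, , drop = FALSE]
  for (i in seq_len(nrow(it))) {
    ev <- it[i, ]
    sh <- .path_shifts(pt, bundle$events, ev$chrom)
    sh <- sh[sh$id != ev$event_id, , drop = FALSE]
    p0 <- .lift_with(sh, ev$site) + ev$tsd_len
    blocks[[length(blocks) + 1]] <- data.frame(
      chrom = ev$chrom, start = p0, end = p0 + nchar(ev$block) + ev$tsd_len,
      stringsAsFactors = FALSE)
  }
  del <- bundle$events$deletions
  dq <- del[del$branch %in% qonly, , drop = FALSE]
  for (i in seq_len(nrow(dq))) {
    ev <- dq[i, ]
    sh <- .path_shifts(pt, bundle$events, ev$chrom)
    blocks[[length(blocks) + 1]] <- data.frame(
      chrom = ev$chrom, start = .lift_with(sh, ev$start),
      end = .lift_with(sh, ev$start) + (ev$end - ev$start),
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0) return(full)
  iv_subtract(full, do.call(rbind, blocks))
}

#' Write a cohort bundle to disk
#'
#' Emits per-sample FASTA, RepeatMasker-dialect annotation, exclusion BED,
#' the ancestral genome, the truth table (JSON) and the tree (newick).
#'
#' @param bundle cohort bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in bundle$samples) {
    write_fasta(unlist(bundle$genomes[[s]]), file.path(dir, paste0(s, ".fa")))
    write_repeat_annotation(bundle$annotations[[s]],
                            file.path(dir, paste0(s, ".out")), "rm_out")
    write_bed(bundle$exclusions[[s]], file.path(dir, paste0(s, ".exclude.bed")))
  }
  write_fasta(unlist(bundle$ancestor_genome), file.path(dir, "ancestor.fa"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
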