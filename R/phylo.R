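# Presence/absence phylogenetics: p-distances, neighbor joining (ape) with
# negative-branch clamping, bootstrap support, rooting on the all-absent
# ancestor, and locus-to-branch assignment.

#' p-distance matrix from a presence matrix
#'
#' The p-distance between two samples is simply the proportion of loci at
#' which their presence states differ (two-state characters, no correction).
#'
#' @param pm presence matrix (loci x samples, including "ancestor").
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(pm) {
  m <- unclass(pm) * 1
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- mean(m[, i] != m[, j])
  }
  d
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Classic Saitou-Nei agglomeration (via ape); negative branch lengths are
#' clamped to zero with the deficit shifted to the sister edge so path
#' lengths are preserved.
#'
#' @param d distance matrix (or dist).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (k in neg) {
    parent <- tr$edge[k, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), k)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[k]
    }
    tr$edge.length[k] <- 0
  }
  tr
}

#' Bootstrap support for a presence-matrix NJ tree
#'
#' Resamples loci with replacement, rebuilds the NJ tree per replicate, and
#' reports the percentage of replicates containing each bipartition of the
#' full-data tree. Also returns the majority-rule consensus, and the
#' full-data tree rooted on the ancestor pseudo-sample with support values as
#' node labels.
#'
#' @param pm presence matrix.
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `tree` (rooted, node labels = support), `support`
#'   (per internal node of the unrooted full-data tree), `consensus`
#'   (majority-rule consensus, rooted on ancestor).
#' @export
bootstrap_support <- function(pm, replicates = 1000L, seed = 1L) {
  set.seed(seed)
  ref <- nj_tree(p_distance_matrix(pm))
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    idx <- sample.int(nrow(pm), nrow(pm), replace = TRUE)
    boots[[b]] <- nj_tree(p_distance_matrix(pm[idx, , drop = FALSE]))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  rooted <- ape::root(ref, outgroup = "ancestor", resolve.root = TRUE)
  # transfer supports: recompute clade counts on the rooted tree's nodes
  rcounts <- ape::prop.clades(rooted, boots, rooted = FALSE)
  rcounts[is.na(rcounts)] <- 0
  rooted$node.label <- round(100 * rcounts / replicates, 1)
  cons <- ape::consensus(boots, p = 0.5)
  if ("ancestor" %in% cons$tip.label)
    cons <- ape::root(cons, outgroup = "ancestor", resolve.root = TRUE)
  list(tree = rooted, support = support, consensus = cons)
}

#' Assign loci to branches of a rooted tree
#'
#' A locus fits the tree when its carrier set equals the full leaf set below
#' exactly one edge of the rooted tree (the ancestor pseudo-sample is
#' excluded from assignment). Fitting loci are counted per edge; the rest are
#' tallied by presence pattern.
#'
#' @param pm presence matrix.
#' @param tree rooted `phylo` tree whose tips are the samples (+ ancestor).
#' @return list with `branch_counts` (edge label = clade pattern, count),
#'   `fit_fraction`, `nonconforming` (pattern counts, sorted), `total`.
#' @export
assign_loci_to_branches <- function(pm, tree) {
  samples <- setdiff(colnames(pm), "ancestor")
  lab <- c(tree$tip.label, rep(NA, tree$Nnode))
  ntip <- length(tree$tip.label)
  clades <- list()
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    tips <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    tips <- setdiff(tips, "ancestor")
    if (length(tips) == 0) next
    clades[[paste(sort(tips), collapse = ",")]] <- k
  }
  pat <- apply(pm[, samples, drop = FALSE], 1, function(r)
    paste(sort(samples[r]), collapse = ","))
  fits <- pat %in% names(clades)
  branch_counts <- table(factor(pat[fits], levels = names(clades)))
  non <- sort(table(pat[!fits]), decreasing = TRUE)
  list(branch_counts = branch_counts,
       fit_fraction = if (length(pat)) mean(fits) else NaN,
       nonconforming = non, total = length(pat))
}
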