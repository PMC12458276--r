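# Multi-sample locus aggregation: callable regions, cross-sample merging in
# outgroup coordinates, sharing profiles, and the presence/absence matrix.

#' Callable regions across all pairwise comparisons
#'
#' Intersection over pairs of the single-contig coverage regions on the
#' outgroup, minus outgroup exclusion regions.
#'
#' @param per_pair_coverage list of interval tables (one per comparison).
#' @param exclusions outgroup exclusion interval table.
#' @return interval table of callable regions.
#' @export
compute_callable <- function(per_pair_coverage, exclusions = interval_df()) {
  stopifnot(length(per_pair_coverage) >= 1)
  cov <- Reduce(iv_intersect, per_pair_coverage)
  iv_subtract(cov, exclusions)
}

#' Merge per-sample loci into cohort loci
#'
#' Single-linkage clustering of locus positions (outgroup coordinates) with
#' gap <= `gap`. A cluster is discarded when it contains more than one
#' distinct underlying variant: more than one element class, or two calls
#' contributed by the same comparison (one event seen in several samples is
#' one variant).
#'
#' Presence states are inferred from the pairwise design: a query sample
#' whose comparison called the variant is present (insertion direction) or
#' absent (deletion direction); the outgroup is present when any comparison
#' called the deletion direction; and a sample whose comparison shows no
#' variant at the locus shares the outgroup state.
#'
#' @param loci data.frame with columns chrom, pos (outgroup coordinate),
#'   carrier (sample carrying the insertion), comparison (query sample of the
#'   originating pairwise comparison), direction ("query" or "target"),
#'   element_class, locus_id.
#' @param gap merge distance in bp.
#' @param samples full sample list (for state inference); when NULL, carriers
#'   are simply the union of per-call carriers.
#' @param outgroup outgroup sample name.
#' @return list with `merged` (one row per retained cohort locus: locus id,
#'   chrom, pos, element_class, carriers) and `discarded` (cluster count).
#' @export
merge_loci <- function(loci, gap = 100L, samples = NULL, outgroup = NULL) {
  if (nrow(loci) == 0)
    return(list(merged = data.frame(cohort_locus = character(),
                                    chrom = character(), pos = integer(),
                                    element_class = character(),
                                    carriers = character(),
                                    stringsAsFactors = FALSE),
                discarded = 0L))
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  newc <- c(TRUE, diff(loci$pos) > gap | loci$chrom[-1] != loci$chrom[-nrow(loci)])
  cl <- cumsum(newc)
  merged <- list(); discarded <- 0L
  for (g in split(seq_len(nrow(loci)), cl)) {
    d <- loci[g, , drop = FALSE]
    multi <- length(unique(d$element_class)) > 1 ||
      anyDuplicated(d$comparison) > 0
    if (multi) { discarded <- discarded + 1L; next }
    if (is.null(samples)) {
      carriers <- sort(unique(d$carrier))
    } else {
      og_present <- any(d$direction == "target")
      carriers <- character(0)
      if (og_present && !is.null(outgroup)) carriers <- outgroup
      for (q in setdiff(samples, outgroup)) {
        k <- which(d$comparison == q)
        present <- if (length(k)) d$direction[k] == "query" else og_present
        if (present) carriers <- c(carriers, q)
      }
      carriers <- sort(carriers)
    }
    merged[[length(merged) + 1]] <- data.frame(
      cohort_locus = sprintf("%s_%d", d$chrom[1], min(d$pos)),
      chrom = d$chrom[1], pos = as.integer(round(mean(d$pos))),
      element_class = d$element_class[1],
      carriers = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  if (is.null(out))
    out <- data.frame(cohort_locus = character(), chrom = character(),
                      pos = integer(), element_class = character(),
                      carriers = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(merged = out, discarded = discarded)
}

#' Build a presence/absence matrix
#'
#' Rows are cohort loci, columns are samples plus a synthetic all-absent
#' "ancestor" pseudo-sample encoding the empty ancestral state.
#'
#' @param merged merged locus table from [merge_loci()].
#' @param samples sample names.
#' @return logical matrix of class `presence_matrix` with the locus table in
#'   attribute "loci".
#' @export
presence_matrix <- function(merged, samples) {
  m <- matrix(FALSE, nrow = nrow(merged), ncol = length(samples) + 1L,
              dimnames = list(merged$cohort_locus, c(samples, "ancestor")))
  if (nrow(merged)) {
    carr <- strsplit(merged$carriers, ",", fixed = TRUE)
    for (i in seq_len(nrow(merged))) m[i, carr[[i]]] <- TRUE
  }
  structure(m, loci = merged, class = c("presence_matrix", "matrix", "array"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x), "loci x", ncol(x), "samples (incl. ancestor)\n")
  sp <- sharing_profile(x)
  cat("  singletons:", sp$singletons, sprintf("(%.1f%%)\n", sp$singleton_pct))
  invisible(x)
}

#' Sharing profile of a presence matrix
#'
#' Exact presence-pattern counts (UpSet-style) plus the singleton summary.
#'
#' @param pm presence matrix.
#' @return list with `patterns` (data.frame pattern/count, sorted by count),
#'   `singletons`, `total`, and `singleton_pct` (percent at 0.1 precision).
#' @export
sharing_profile <- function(pm) {
  samples <- setdiff(colnames(pm), "ancestor")
  sub <- pm[, samples, drop = FALSE]
  pat <- apply(sub, 1, function(r) paste(samples[r], collapse = ","))
  counts <- table(pat)
  df <- data.frame(pattern = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count), , drop = FALSE]
  rownames(df) <- NULL
  n1 <- sum(rowSums(sub) == 1)
  list(patterns = df, singletons = n1, total = nrow(sub),
       singleton_pct = singleton_percent(n1, nrow(sub)))
}

#' Singleton percentage at printed precision
#' @param singletons,total counts.
#' @return percent rounded to 0.1.
#' @export
singleton_percent <- function(singletons, total) {
  if (total == 0) return(NaN)
  round(100 * singletons / total, 1)
}
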