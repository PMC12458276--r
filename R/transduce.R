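# 3' transduction tracing. A LINE-1 with transcriptional read-through carries
# downstream sequence from its parent locus; the tail between the LINE-1
# annotation and the variant end fingerprints the parent. Candidates are
# masked for low complexity (DUST-style) and searched against the outgroup
# genome with a deterministic seed-and-extend aligner standing in for blat.

#' Extract a candidate 3' transduction from a refined LINE-1 locus
#'
#' The sequence from the 3' end of the longest intersecting LINE-1
#' annotation to the end of the refined insert, read in element orientation
#' (the refined insert excludes TSD copies, so TSDs never enter candidates).
#'
#' @param filled_seq filled-genome chromosome sequence.
#' @param chrom chromosome.
#' @param insert_start,insert_end refined insert interval.
#' @param orientation element orientation ("+" or "-").
#' @param annotations filled-genome annotation table.
#' @param min_len minimum candidate length in bp.
#' @return list with seq, start, end (filled coordinates) or NULL when no
#'   LINE-1 annotation intersects or the tail is shorter than `min_len`.
#' @export
extract_transduction_candidate <- function(filled_seq, chrom, insert_start,
                                           insert_end, orientation,
                                           annotations, min_len = 25L) {
  if (!orientation %in% c("+", "-")) return(NULL)
  a <- annotations[annotations$chrom == chrom &
                     grepl("^LINE", annotations$repeat_class), , drop = FALSE]
  if (nrow(a) == 0) return(NULL)
  ov <- pmin(a$end, insert_end) - pmax(a$start, insert_start)
  a <- a[ov > 0, , drop = FALSE]; ov <- ov[ov > 0]
  if (nrow(a) == 0) return(NULL)
  best <- a[which.max(ov), ]
  if (orientation == "+") {
    lo <- min(max(best$end, insert_start), insert_end); hi <- insert_end
    s <- substr0(filled_seq, lo, hi)
  } else {
    lo <- insert_start; hi <- max(min(best$start, insert_end), insert_start)
    s <- revcomp(substr0(filled_seq, lo, hi))
  }
  if (nchar(s) < min_len) return(NULL)
  list(seq = s, start = as.integer(lo), end = as.integer(hi))
}

#' DUST-style low-complexity mask
#'
#' Sliding 64 bp windows are scored by triplet over-representation
#' (10 * sum c(c-1)/2 / (k-1) over triplet counts c, k triplets per window).
#' In windows exceeding `threshold`, the positions spanned by repeated
#' triplets are masked (an approximation of sdust's perfect intervals that
#' confines the mask to the low-complexity tract itself).
#'
#' @param seq nucleotide string.
#' @param window window size in bp.
#' @param threshold masking score threshold.
#' @return logical vector (TRUE = masked) of length nchar(seq).
#' @export
dust_mask <- function(seq, window = 64L, threshold = 20) {
  n <- nchar(seq)
  mask <- rep(FALSE, n)
  if (n < 3) return(mask)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  tri <- paste0(v[seq_len(n - 2)], v[seq_len(n - 2) + 1L], v[seq_len(n - 2) + 2L])
  starts <- seq.int(1L, max(1L, n - window + 1L))
  for (st in starts) {
    en <- min(n, st + window - 1L)
    k <- en - st - 1L          # triplets fully inside the window
    if (k < 2) next
    win_tri <- tri[st:(st + k - 1L)]
    counts <- table(win_tri)
    score <- 10 * sum(counts * (counts - 1) / 2) / (k - 1)
    if (score > threshold) {
      # confine the mask to dense tracts: runs of >= 5 consecutive
      # over-represented triplets
      rep_tri <- names(counts)[counts >= 3]
      hit <- which(win_tri %in% rep_tri)
      if (length(hit) == 0) next
      r <- rle(diff(c(-10L, hit)) == 1L)
      ends <- cumsum(r$lengths)
      for (k in which(r$values & r$lengths >= 4L)) {
        run <- hit[(ends[k] - r$lengths[k]):ends[k]]
        lo <- min(run) + st - 1L; hi <- max(run) + st + 1L
        mask[lo:hi] <- TRUE
      }
    }
  }
  mask
}

#' Mask a transduction candidate for low complexity
#'
#' @param candidate list from [extract_transduction_candidate()].
#' @param extra_mask optional logical vector of additional masked positions
#'   (e.g. element-library matches).
#' @param min_unmasked minimum unmasked bp for the candidate to survive.
#' @return candidate with `mask` (logical) and `unmasked_bp` added, or NULL
#'   when fewer than `min_unmasked` bp remain. The original, unmasked
#'   sequence is what gets searched.
#' @export
mask_low_complexity <- function(candidate, extra_mask = NULL,
                                min_unmasked = 25L) {
  if (is.null(candidate)) return(NULL)
  mask <- dust_mask(candidate$seq)
  if (!is.null(extra_mask)) mask <- mask | extra_mask
  candidate$mask <- mask
  candidate$unmasked_bp <- sum(!mask)
  if (candidate$unmasked_bp < min_unmasked) return(NULL)
  candidate
}

# seed-and-extend alignment of a query against one strand of the genome
.seed_hits <- function(q, genome, k = 11L, stride = 5L) {
  n <- nchar(q)
  if (n < k) return(NULL)
  seed_pos <- unique(c(seq.int(1L, n - k + 1L, by = stride), n - k + 1L))
  rows <- list()
  for (ch in names(genome)) {
    for (sp in seed_pos) {
      seed <- substr(q, sp, sp + k - 1L)
      m <- gregexpr(seed, genome[[ch]], fixed = TRUE)[[1]]
      if (m[1] == -1) next
      if (length(m) > 200) next   # hyper-repetitive seed
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, diag = as.integer(m) - sp,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Search a candidate transduction against a genome
#'
#' Deterministic seed-and-extend (11-mer exact seeds, gapped extension with
#' match +1 / mismatch -2 / gap open -4 / gap extend -1) over both strands.
#' Hits are kept when identity >= `min_identity`, matching bases >=
#' `min_match`, the target is on an allowed chromosome, the target lies more
#' than `self_exclusion` bp from the source locus, the target span is within
#' 100 bp of the query length, and at least `min_unmasked_aligned` unmasked
#' query bases are aligned. The candidate is voided (empty result, attribute
#' `voided`) when more than `max_hits` raw alignments are produced.
#'
#' @param candidate masked candidate from [mask_low_complexity()].
#' @param genome named list of chromosome sequences (the outgroup).
#' @param self_chrom,self_start,self_end the dimorphic locus in outgroup
#'   coordinates (for self-exclusion).
#' @param chroms allowed chromosome names.
#' @param min_identity,min_match,span_slack,self_exclusion,max_hits,
#'   min_unmasked_aligned filter thresholds.
#' @return data.frame of hits: chrom, start, end, strand, identity, match_bp.
#' @export
search_genome <- function(candidate, genome, self_chrom = NA, self_start = NA,
                          self_end = NA, chroms = names(genome),
                          min_identity = 0.95, min_match = 25L,
                          span_slack = 100L, self_exclusion = 10000L,
                          max_hits = 50L, min_unmasked_aligned = 25L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      match_bp = integer(), stringsAsFactors = FALSE)
  if (is.null(candidate)) return(empty)
  qlen <- nchar(candidate$seq)
  aligns <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") candidate$seq else revcomp(candidate$seq)
    seeds <- .seed_hits(q, genome)
    if (is.null(seeds)) next
    seeds <- seeds[order(seeds$chrom, seeds$diag), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(seeds$diag) > 50 |
                      seeds$chrom[-1] != seeds$chrom[-nrow(seeds)]))
    for (g in split(seq_len(nrow(seeds)), grp)) {
      ch <- seeds$chrom[g[1]]
      d0 <- min(seeds$diag[g])
      lo <- max(1L, d0 - 50L)
      hi <- min(nchar(genome[[ch]]), d0 + qlen + 150L)
      subject <- substr(genome[[ch]], lo, hi)
      al <- Biostrings::pairwiseAlignment(
        q, subject, type = "local",
        substitutionMatrix = .nuc_mat(), gapOpening = 4, gapExtension = 1)
      if (Biostrings::score(al) <= 0) next
      pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
      alen <- nchar(as.character(pat))
      nmat <- Biostrings::nmatch(al)
      tstart <- lo + Biostrings::start(sub) - 2L      # 0-based
      tend <- lo + Biostrings::end(sub) - 1L
      qs <- Biostrings::start(pat); qe <- Biostrings::end(pat)
      if (strand == "-") { tmp <- qs; qs <- qlen - qe + 1L; qe <- qlen - tmp + 1L }
      aligns[[length(aligns) + 1]] <- data.frame(
        chrom = ch, start = tstart, end = tend, strand = strand,
        identity = nmat / alen, match_bp = nmat, q_start = qs, q_end = qe,
        stringsAsFactors = FALSE)
    }
  }
  if (length(aligns) == 0) return(empty)
  hits <- do.call(rbind, aligns)
  # deduplicate overlapping windows: keep the best alignment per target region
  hits <- hits[order(hits$chrom, hits$start, -hits$match_bp), , drop = FALSE]
  dup <- logical(nrow(hits))
  if (nrow(hits) > 1) for (i in 2:nrow(hits)) {
    prev <- max(which(!dup[seq_len(i - 1)]))
    dup[i] <- hits$chrom[i] == hits$chrom[prev] &&
      hits$start[i] < hits$end[prev] && hits$strand[i] == hits$strand[prev]
  }
  hits <- hits[!dup, , drop = FALSE]
  if (nrow(hits) > max_hits) {
    out <- empty; attr(out, "voided") <- TRUE
    return(out)
  }
  unmasked <- !candidate$mask
  keep <- hits$identity >= min_identity & hits$match_bp >= min_match &
    hits$chrom %in% chroms &
    abs((hits$end - hits$start) - qlen) <= span_slack &
    vapply(seq_len(nrow(hits)), function(i)
      sum(unmasked[hits$q_start[i]:hits$q_end[i]]), 0L) >= min_unmasked_aligned
  if (!is.na(self_chrom)) {
    same <- hits$chrom == self_chrom
    gap <- pmax(self_start - hits$end, hits$start - self_end, 0)
    keep <- keep & !(same & gap <= self_exclusion)
  }
  out <- hits[keep, c("chrom", "start", "end", "strand", "identity",
                      "match_bp"), drop = FALSE]
  rownames(out) <- NULL
  out
}

.nuc_mat <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(-2, 4, 4, dimnames = list(b, b))
  diag(m) <- 1
  m
}

#' Cluster transduction hits into sources and test parent adjacency
#'
#' A hit is parent-adjacent when an outgroup LINE-1 annotation lies within
#' `window` bp, is not wholly inside (or containing) the hit, sits upstream
#' of the hit in the annotation's orientation (the transduction is read
#' through the element's 3' end), and is orientation-concordant. Hits merged
#' at gap <= `merge_gap` form source clusters; clusters backing more than one
#' independent insertion are flagged recurrent.
#'
#' @param hits data.frame of hits across samples with columns chrom, start,
#'   end, strand, sample, locus_id.
#' @param annotations outgroup annotation table.
#' @param window parent adjacency window in bp.
#' @param merge_gap source cluster merge distance.
#' @return list with `hits` (parent_adjacent and source_cluster added) and
#'   `clusters` (cluster extents, event counts, recurrent flag).
#' @export
classify_sources <- function(hits, annotations, window = 50L,
                             merge_gap = 100L) {
  if (nrow(hits) == 0)
    return(list(hits = cbind(hits, parent_adjacent = logical(0),
                             source_cluster = character(0)),
                clusters = data.frame(source_cluster = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), n_events = integer(),
                                      recurrent = logical(),
                                      stringsAsFactors = FALSE)))
  l1 <- annotations[grepl("^LINE", annotations$repeat_class), , drop = FALSE]
  hits$parent_adjacent <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    a <- l1[l1$chrom == h$chrom, , drop = FALSE]
    if (nrow(a) == 0) return(FALSE)
    inside <- a$start >= h$start & a$end <= h$end
    contains <- a$start <= h$start & a$end >= h$end
    a <- a[!inside & !contains, , drop = FALSE]
    if (nrow(a) == 0) return(FALSE)
    plus_ok <- a$strand == "+" & h$start >= a$end - 5L &
      (h$start - a$end) <= window & h$strand == a$strand
    minus_ok <- a$strand == "-" & h$end <= a$start + 5L &
      (a$start - h$end) <= window & h$strand == a$strand
    any(plus_ok | minus_ok)
  }, logical(1))
  merged <- iv_merge(hits[, c("chrom", "start", "end")], gap = merge_gap)
  merged$source_cluster <- sprintf("src_%s_%d", merged$chrom, merged$start)
  idx <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    j <- which(merged$chrom == hits$chrom[i] &
                 merged$start <= hits$start[i] & merged$end >= hits$end[i])
    idx[i] <- j[1]
  }
  hits$source_cluster <- merged$source_cluster[idx]
  ev <- paste(hits$sample, hits$locus_id)
  n_events <- vapply(split(ev, hits$source_cluster), function(x)
    length(unique(x)), 0L)
  merged$n_events <- as.integer(n_events[merged$source_cluster])
  merged$n_events[is.na(merged$n_events)] <- 0L
  merged$recurrent <- merged$n_events > 1
  list(hits = hits, clusters = merged)
}
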