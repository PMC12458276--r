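# Hallmarks of target-primed reverse transcription: element orientation from
# annotation votes, 3' poly(A) tails, endonuclease cleavage sites, and the
# stringent / relaxed hallmark classification.

#' Detect element orientation from annotation segments
#'
#' Annotation segments of at least `min_segment` bp overlapping the insert
#' vote; a unanimous vote gives the strand, conflicting votes give
#' "ambiguous" (locus retained, poly(A) skipped), and no qualifying segment
#' gives "removed".
#'
#' @param annotations filled-genome annotation table.
#' @param chrom chromosome.
#' @param insert_start,insert_end refined insert interval (between TSDs).
#' @param min_segment minimum overlap in bp for a segment to vote.
#' @return "+", "-", "ambiguous" or "removed".
#' @export
detect_orientation <- function(annotations, chrom, insert_start, insert_end,
                               min_segment = 20L) {
  seg <- .insert_segments(annotations, chrom, insert_start, insert_end,
                          min_segment)
  if (nrow(seg) == 0) return("removed")
  s <- unique(seg$strand)
  if (length(s) == 1) s else "ambiguous"
}

.insert_segments <- function(annotations, chrom, insert_start, insert_end,
                             min_segment = 20L) {
  a <- annotations[annotations$chrom == chrom &
                     grepl("^(SINE|LINE)", annotations$repeat_class), ,
                   drop = FALSE]
  if (nrow(a) == 0) return(a)
  ov_start <- pmax(a$start, insert_start)
  ov_end <- pmin(a$end, insert_end)
  a[ov_end - ov_start >= min_segment, , drop = FALSE]
}

#' Detect a 3' poly(A) tail in a refined insert
#'
#' Searches the sequence between TSDs (or to the insert boundary) for
#' homopolymer runs of A (plus orientation) or T (minus orientation) whose
#' gap to the element's 3' junction is at most `max_gap` bases. Among
#' eligible runs the longest wins (ties: the run nearer the junction); runs
#' shorter than `min_len` are not reported.
#'
#' @param insert_seq sequence between TSDs.
#' @param orientation "+" or "-" (the 3' junction is the right insert edge
#'   for plus loci and the left edge for minus loci).
#' @param max_gap maximum gap to the junction in bp.
#' @param min_len minimum reported poly(A) length.
#' @return list with polya_len (0 if none) and polya_gap (NA if none).
#' @export
detect_polya <- function(insert_seq, orientation, max_gap = 5L, min_len = 10L) {
  none <- list(polya_len = 0L, polya_gap = NA_integer_)
  if (!orientation %in% c("+", "-") || !nzchar(insert_seq)) return(none)
  base <- if (orientation == "+") "A" else "T"
  v <- strsplit(insert_seq, "", fixed = TRUE)[[1]]
  r <- rle(v == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) return(none)
  n <- length(v)
  gap <- if (orientation == "+") n - ends[runs] else starts[runs] - 1L
  len <- r$lengths[runs]
  ok <- gap <= max_gap
  if (!any(ok)) return(none)
  len <- len[ok]; gap <- gap[ok]
  pick <- order(-len, gap)[1]
  if (len[pick] < min_len) return(none)
  list(polya_len = as.integer(len[pick]), polya_gap = as.integer(gap[pick]))
}

#' Extract the endonuclease cleavage site 7-mer
#'
#' Reported on the minus strand so a canonical site reads TTTTTAA: for plus
#' loci, the reverse complement of the two bases upstream of the 5' TSD plus
#' the first five TSD bases; for minus loci, the mirrored window (last five
#' bases of the right TSD plus two downstream bases) read on the plus strand.
#' Only defined for loci with a TSD of at least `min_tsd` bp and a resolved
#' orientation.
#'
#' @param filled_seq filled-genome chromosome sequence.
#' @param insert_start,insert_end refined insert interval (between TSDs).
#' @param tsd_len called TSD length.
#' @param orientation "+" or "-".
#' @param min_tsd minimum TSD length.
#' @return 7-character string, or NA when undefined.
#' @export
extract_en_site <- function(filled_seq, insert_start, insert_end, tsd_len,
                            orientation, min_tsd = 10L) {
  if (tsd_len < min_tsd || !orientation %in% c("+", "-")) return(NA_character_)
  n <- nchar(filled_seq)
  if (orientation == "+") {
    lo <- insert_start - tsd_len - 2L
    if (lo < 0) return(NA_character_)
    revcomp(substr0(filled_seq, lo, lo + 7L))
  } else {
    lo <- insert_end + tsd_len - 5L
    if (lo + 7L > n) return(NA_character_)
    substr0(filled_seq, lo, lo + 7L)
  }
}

#' Classify hallmark evidence at a locus
#'
#' Stringent mode follows the high-confidence thresholds (TSD >= 10 bp,
#' poly(A) >= 10 bp with gap <= 5 bp). Relaxed mode counts TSDs of at least
#' 7 bp and accepts degraded poly(A) evidence: any 15 bp window containing at
#' least 10 orientation-appropriate bases within 30 bp of the TSD (or of the
#' insert end when no TSD of >= 7 bp exists).
#'
#' @param tsd_len called TSD length.
#' @param polya_len,polya_gap stringent poly(A) call from [detect_polya()].
#' @param orientation "+", "-" or "ambiguous".
#' @param insert_seq sequence between TSDs (used for relaxed windows).
#' @param mode "stringent" or "relaxed".
#' @param min_tsd,min_polya,max_gap stringent thresholds.
#' @param relaxed_min_tsd,relaxed_window,relaxed_min_a,relaxed_range relaxed
#'   thresholds (window size, required base count, allowed distance).
#' @return one of "both", "tsd_only", "polya_only", "neither", "ambiguous".
#' @export
classify_hallmarks <- function(tsd_len, polya_len, polya_gap, orientation,
                               insert_seq = "",
                               mode = c("stringent", "relaxed"),
                               min_tsd = 10L, min_polya = 10L, max_gap = 5L,
                               relaxed_min_tsd = 7L, relaxed_window = 15L,
                               relaxed_min_a = 10L, relaxed_range = 30L) {
  mode <- match.arg(mode)
  if (!orientation %in% c("+", "-")) return("ambiguous")
  if (mode == "stringent") {
    has_tsd <- tsd_len >= min_tsd
    has_pa <- polya_len >= min_polya && !is.na(polya_gap) && polya_gap <= max_gap
  } else {
    has_tsd <- tsd_len >= relaxed_min_tsd
    has_pa <- .relaxed_polya(insert_seq, orientation, relaxed_window,
                             relaxed_min_a, relaxed_range)
  }
  if (has_tsd && has_pa) "both"
  else if (has_tsd) "tsd_only"
  else if (has_pa) "polya_only"
  else "neither"
}

# any window of `w` bp with >= `k` orientation bases whose distance from the
# 3' junction is at most `range` bp
.relaxed_polya <- function(insert_seq, orientation, w = 15L, k = 10L,
                           range = 30L) {
  n <- nchar(insert_seq)
  if (n < w) return(FALSE)
  base <- if (orientation == "+") "A" else "T"
  v <- strsplit(insert_seq, "", fixed = TRUE)[[1]] == base
  region_len <- min(n, w + range)
  idx <- if (orientation == "+") (n - region_len + 1L):n else 1:region_len
  x <- v[idx]
  cs <- cumsum(x)
  counts <- cs[w:length(x)] - c(0, cs)[seq_len(length(x) - w + 1L)]
  any(counts >= k)
}

#' Assign a repeat subfamily to a refined locus
#'
#' Intersects the between-TSD interval with genome annotations; segments
#' shorter than `min_segment` bp are ignored, SINEC_Cf and SINEC2A1_Cf
#' collapse to the merged label "SINEC_Cf/2A1", and loci overlapping several
#' distinct subfamilies are "unresolved".
#'
#' @param annotations filled-genome annotation table.
#' @param chrom chromosome.
#' @param insert_start,insert_end refined insert interval.
#' @param min_segment minimum overlap in bp.
#' @return subfamily label, "unresolved", or "" when no qualifying segment.
#' @export
assign_subfamily <- function(annotations, chrom, insert_start, insert_end,
                             min_segment = 20L) {
  seg <- .insert_segments(annotations, chrom, insert_start, insert_end,
                          min_segment)
  if (nrow(seg) == 0) return("")
  fam <- unique(ifelse(seg$subfamily %in% c("SINEC_Cf", "SINEC2A1_Cf"),
                       "SINEC_Cf/2A1", seg$subfamily))
  if (length(fam) > 1) "unresolved" else fam
}

#' Base-count matrix of endonuclease cleavage sites
#'
#' @param en_sites character vector of 7-mers (NA entries dropped).
#' @return 4 x 7 integer matrix (rows A, C, G, T; columns motif positions);
#'   each column sums to the number of sites.
#' @export
logo_matrix <- function(en_sites) {
  en_sites <- en_sites[!is.na(en_sites) & nchar(en_sites) == 7]
  m <- matrix(0L, nrow = 4, ncol = 7,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  if (length(en_sites) == 0) return(m)
  chars <- do.call(rbind, strsplit(en_sites, "", fixed = TRUE))
  for (p in 1:7) {
    tb <- table(factor(chars[, p], levels = c("A", "C", "G", "T")))
    m[, p] <- as.integer(tb)
  }
  m
}
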