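# Split-alignment breakpoint refinement. The filled and empty alleles are
# compared positionally: prefix and suffix +1/-1 identity score arrays are
# computed, the split maximizing left[i] + right[j] is chosen, and each
# breakpoint is snapped to the end of a >=20 bp exact-identity run so that
# isolated chance matches beyond the true junction cannot drag the breakpoint
# (a pure +1/-1 argmax walks past the junction with appreciable probability).
# The insert block is the filled sequence between the two flanks; the TSD may
# make the flanks overlap the empty allele (left[i] and right[j] can together
# cover more than the empty window).

# prefix score + candidate run-end breakpoints for two raw vectors
.flank_scores <- function(a, b, min_run = 20L) {
  n <- min(length(a), length(b))
  if (n == 0) return(list(P = numeric(0), cand = 0L))
  m <- a[seq_len(n)] == b[seq_len(n)]
  P <- cumsum(ifelse(m, 1, -1))
  r <- rle(as.vector(m))
  ends <- cumsum(r$lengths)
  cand <- ends[r$values & r$lengths >= min_run]
  list(P = P, cand = c(0L, cand))
}

# choose breakpoints (i = left flank length, j = right flank length)
.split_breakpoints <- function(fwin, ewin, min_run = 20L) {
  fa <- charToRaw(fwin); ea <- charToRaw(ewin)
  left <- .flank_scores(fa, ea, min_run)
  right <- .flank_scores(rev(fa), rev(ea), min_run)
  score <- function(S, k) if (k == 0) 0 else S$P[k]
  nF <- length(fa)
  best <- NULL
  for (i in left$cand) for (j in right$cand) {
    if (i + j > nF) next
    s <- score(left, i) + score(right, j)
    if (is.null(best) || s > best$s ||
        (s == best$s && i < best$i)) best <- list(i = i, j = j, s = s)
  }
  best
}

#' Refine one candidate locus by split alignment of filled vs empty alleles
#'
#' Extracts the filled and empty alleles with flanking sequence, aligns the
#' left flanks prefix-wise and the right flanks suffix-wise, and places the
#' insertion breakpoints at the split maximizing total flank identity. If the
#' refined junction is more than `max_shift` bp from the input coordinate the
#' refinement is retried down a ladder of flank sizes; it is accepted early
#' when two successive flank sizes agree on the same absolute junction.
#' Target site duplications and target site deletions are then called by
#' exact three-way comparison ([call_tsd()]).
#'
#' @param filled_seq chromosome sequence of the genome carrying the insertion.
#' @param empty_seq chromosome sequence of the genome lacking it.
#' @param filled_pos approximate 0-based start of the inserted block in the
#'   filled genome.
#' @param empty_pos approximate 0-based junction in the empty genome.
#' @param sv_len approximate insertion length.
#' @param flanks ladder of flank sizes to try.
#' @param max_shift maximum accepted distance between refined junction and
#'   input coordinate before retrying.
#' @param min_insert_len QC: minimum refined insert length.
#' @param min_non_tsd QC: minimum inserted bp not called as TSD.
#' @param min_flank minimum usable flank after clipping at contig ends.
#' @param tsd_max_mismatch allowed mismatches in the three-way TSD comparison
#'   (0 = the exact-match contract).
#' @return a one-row data.frame: qc_pass, qc_reason, flank_used, insert_start,
#'   insert_end (filled-genome coordinates of the block between TSDs),
#'   refined_junction (empty-genome coordinate), insert_seq, tsd_seq, tsd_len,
#'   ts_del_len, non_tsd_bp, insert_len.
#' @export
refine_locus <- function(filled_seq, empty_seq, filled_pos, empty_pos, sv_len,
                         flanks = c(1000L, 500L, 250L, 125L), max_shift = 150L,
                         min_insert_len = 50L, min_non_tsd = 30L,
                         min_flank = 50L, tsd_max_mismatch = 0L) {
  if (!nzchar(filled_seq) || !nzchar(empty_seq))
    stop("filled and empty sequences are required")
  nfil <- nchar(filled_seq); nemp <- nchar(empty_seq)
  fail <- function(reason) data.frame(
    qc_pass = FALSE, qc_reason = reason, flank_used = NA_integer_,
    insert_start = NA_integer_, insert_end = NA_integer_,
    refined_junction = NA_integer_, insert_seq = "", tsd_seq = "",
    tsd_len = 0L, ts_del_len = 0L, non_tsd_bp = NA_integer_,
    insert_len = NA_integer_, stringsAsFactors = FALSE)
  prev_junction <- NULL
  accepted <- NULL
  for (f in flanks) {
    fl <- min(f, filled_pos, empty_pos)
    rl <- min(f, nfil - (filled_pos + sv_len), nemp - empty_pos)
    if (fl < min_flank || rl < min_flank) return(fail("flank"))
    fs <- filled_pos - fl; es <- empty_pos - fl
    ewin <- substr0(empty_seq, es, empty_pos + rl)
    # anchor the filled window's right end on the empty window's terminal
    # sequence, so target-site deletions or length jitter cannot misalign the
    # suffix comparison
    fend <- filled_pos + sv_len + rl
    tail_k <- min(30L, rl)
    etail <- substr(ewin, nchar(ewin) - tail_k + 1L, nchar(ewin))
    lo <- max(fs, fend - 500L); hi <- min(nfil, fend + 500L)
    m <- gregexpr(etail, substr0(filled_seq, lo, hi), fixed = TRUE)[[1]]
    if (m[1] != -1) {
      ends <- lo + as.integer(m) - 1L + tail_k   # candidate 0-based ends
      fend <- ends[which.min(abs(ends - fend))]
    }
    fwin <- substr0(filled_seq, fs, fend)
    bp <- .split_breakpoints(fwin, ewin)
    if (is.null(bp)) { prev_junction <- NULL; next }
    junction <- es + bp$i
    # both flanks must anchor on exact identity, and the implied insert block
    # must be consistent with the call length; violations mean another
    # variant sits inside the window, so descend the ladder
    blk <- nchar(fwin) - bp$i - bp$j
    if (bp$i < min_flank || bp$j < min_flank || blk - sv_len > max_shift) {
      prev_junction <- NULL; next
    }
    if (abs(junction - empty_pos) <= max_shift ||
        (!is.null(prev_junction) && junction == prev_junction)) {
      accepted <- list(f = f, fs = fs, es = es, fwin = fwin, ewin = ewin,
                       i = bp$i, j = bp$j, junction = junction)
      break
    }
    prev_junction <- junction
  }
  if (is.null(accepted)) return(fail("discordant"))
  a <- accepted
  nF <- nchar(a$fwin); nE <- nchar(a$ewin)
  tsd <- call_tsd(a$fwin, a$ewin, a$i, a$j, max_mismatch = tsd_max_mismatch)
  non_tsd <- nF - a$i - a$j
  if (non_tsd < 0) return(fail("discordant"))
  insert_len <- non_tsd + tsd$tsd_len
  out <- data.frame(
    qc_pass = TRUE, qc_reason = "", flank_used = as.integer(a$f),
    insert_start = as.integer(a$fs + a$i),
    insert_end = as.integer(a$fs + nF - a$j),
    refined_junction = as.integer(a$junction),
    insert_seq = substr(a$fwin, a$i + 1L, nF - a$j), tsd_seq = tsd$tsd_seq,
    tsd_len = tsd$tsd_len, ts_del_len = tsd$ts_del_len,
    non_tsd_bp = as.integer(non_tsd), insert_len = as.integer(insert_len),
    stringsAsFactors = FALSE)
  if (insert_len < min_insert_len) {
    out$qc_pass <- FALSE; out$qc_reason <- "short"
  } else if (non_tsd < min_non_tsd) {
    out$qc_pass <- FALSE; out$qc_reason <- "low_non_tsd"
  }
  out
}

#' Call a target site duplication or target site deletion at a refined split
#'
#' The TSD is the longest string that is simultaneously a suffix of the left
#' breakpoint flank, a prefix of the right breakpoint flank, and present once
#' at the empty-site junction (three-way exact identity by default). If the
#' flanks together cover less than the empty window, the uncovered empty bases
#' are a target site deletion.
#'
#' @param fwin,ewin filled and empty windows (left flanks position-aligned,
#'   right flanks end-aligned).
#' @param i,j left and right flank lengths from the split.
#' @param max_tsd maximum TSD length searched.
#' @param max_mismatch allowed mismatches per pairwise comparison.
#' @return list with tsd_seq, tsd_len, ts_del_len.
#' @export
call_tsd <- function(fwin, ewin, i, j, max_tsd = 500L, max_mismatch = 0L) {
  nF <- nchar(fwin); nE <- nchar(ewin)
  ts_del <- max(0L, nE - i - j)
  L <- nF - nE                 # net inserted bases; the downstream TSD copy
  tmax <- min(i, L, max_tsd)   # ends the inserted block at position i + L
  best <- 0L
  # an empty-side remainder between the flanks is a target site deletion;
  # a duplication (flank overlap) is then excluded
  if (ts_del > 0) tmax <- 0L
  if (tmax >= 1 && i + L <= nF) {
    for (t in seq_len(tmax)) {
      left <- substr(fwin, i - t + 1L, i)
      right <- substr(fwin, i + L - t + 1L, i + L)
      empty <- substr(ewin, i - t + 1L, i)
      if (.mm(left, right) <= max_mismatch && .mm(left, empty) <= max_mismatch)
        best <- t
    }
  }
  if (best > 0) ts_del <- 0L
  list(tsd_seq = if (best > 0) substr(fwin, i - best + 1L, i) else "",
       tsd_len = best, ts_del_len = as.integer(ts_del))
}

.mm <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(charToRaw(a) != charToRaw(b))
}

#' LINE-1 false-positive filters
#'
#' Internal deletions of pre-existing LINE-1s masquerade as dimorphic LINE-1
#' insertions. Two filters remove them: (1) the refined insert itself must be
#' at least `min_frac` covered by LINE-1 annotation (HAL-family LINEs never
#' count); (2) loci where an annotation segment extends beyond the refined
#' insert (the "insert" is embedded in a larger annotated LINE-1) must have a
#' TSD of at least `min_tsd` bp.
#'
#' @param refined one-row refined locus (from [refine_locus()]) with
#'   insert_start/insert_end in filled-genome coordinates.
#' @param annotations filled-genome annotation table.
#' @param chrom chromosome of the locus.
#' @param min_frac minimum LINE-1 fraction of the insert.
#' @param min_tsd minimum TSD for embedded loci.
#' @return the refined row with qc_pass/qc_reason updated.
#' @export
apply_line1_fp_filters <- function(refined, annotations, chrom,
                                   min_frac = 0.7, min_tsd = 10L) {
  if (!refined$qc_pass) return(refined)
  iv <- interval_df(chrom, refined$insert_start, refined$insert_end)
  l1 <- annotations[grepl("^LINE", annotations$repeat_class) &
                      !grepl("^HAL", annotations$subfamily) &
                      annotations$chrom == chrom, , drop = FALSE]
  cov <- if (nrow(l1)) iv_covered_bp(iv, l1) else 0L
  if (cov < min_frac * (refined$insert_end - refined$insert_start)) {
    refined$qc_pass <- FALSE; refined$qc_reason <- "low_l1_content"
    return(refined)
  }
  if (nrow(l1)) {
    ov <- l1$start < refined$insert_end & l1$end > refined$insert_start
    extends <- ov & (l1$start < refined$insert_start | l1$end > refined$insert_end)
    if (any(extends) && refined$tsd_len < min_tsd) {
      refined$qc_pass <- FALSE; refined$qc_reason <- "embedded_no_tsd"
    }
  }
  refined
}
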