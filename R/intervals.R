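# Interval utilities. Intervals are data.frames with columns chrom, start, end
# (0-based, half-open). All set operations delegate to IRanges per chromosome.

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further columns recycled alongside.
#' @return data.frame with columns chrom, start, end (plus extras).
#' @export
interval_df <- function(chrom = character(), start = integer(), end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must not be NA")
  if (any(df$start < 0) || any(df$start > df$end))
    stop("intervals must satisfy 0 <= start <= end")
  if (any(!nzchar(df$chrom))) stop("chrom names must be non-empty")
  invisible(df)
}

# 0-based half-open -> IRanges (1-based closed)
.ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

.split_chrom <- function(df) split(seq_len(nrow(df)), df$chrom)

#' Merge overlapping or nearby intervals
#'
#' Single-linkage merge of intervals on the same chromosome whose edge gap is
#' at most `gap` bases (gap = 0 merges book-ended and overlapping intervals).
#'
#' @param df interval table.
#' @param gap maximum number of bases between merged intervals.
#' @return merged interval table sorted by chrom, start.
#' @export
iv_merge <- function(df, gap = 0L) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(.ir(d), min.gapwidth = gap + 1L)
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Subtract one interval set from another
#'
#' @param a,b interval tables; every region of `a` overlapped by `b` is removed.
#' @return interval table of the remaining pieces of `a`.
#' @export
iv_subtract <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  pieces <- lapply(split(a, a$chrom), function(d) {
    bb <- b[b$chrom == d$chrom[1], , drop = FALSE]
    if (nrow(bb) == 0) return(d[, c("chrom", "start", "end")])
    r <- IRanges::setdiff(.ir(d), IRanges::reduce(.ir(bb)))
    if (length(r) == 0) return(NULL)
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(a[0, c("chrom", "start", "end")])
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect two interval sets
#' @param a,b interval tables.
#' @return interval table covering bases present in both.
#' @export
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, c("chrom", "start", "end")])
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  pieces <- lapply(chroms, function(ch) {
    r <- IRanges::intersect(
      IRanges::reduce(.ir(a[a$chrom == ch, , drop = FALSE])),
      IRanges::reduce(.ir(b[b$chrom == ch, , drop = FALSE])))
    if (length(r) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(a[0, c("chrom", "start", "end")])
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Total length of an interval set (after merging overlaps)
#' @param df interval table.
#' @return total number of covered bases.
#' @export
iv_total_len <- function(df) {
  if (nrow(df) == 0) return(0L)
  m <- iv_merge(df)
  sum(m$end - m$start)
}

#' Per-interval covered basepairs
#'
#' For each row of `a`, the number of its bases covered by the union of `b`.
#'
#' @param a,b interval tables.
#' @return integer vector parallel to rows of `a`.
#' @export
iv_covered_bp <- function(a, b) {
  if (nrow(a) == 0) return(integer(0))
  out <- integer(nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    rb <- IRanges::reduce(.ir(bb))
    ra <- .ir(a[ia, , drop = FALSE])
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    w <- IRanges::width(IRanges::pintersect(ra[qi], rb[S4Vectors::subjectHits(hits)]))
    out[ia] <- out[ia] + as.integer(tapply(w, factor(qi, levels = seq_along(ra)),
                                           sum, default = 0L))
  }
  out
}

#' Edge distance to the nearest interval of another set
#'
#' Distance between closest edges: 0 for overlapping or book-ended intervals,
#' otherwise the number of bases strictly between the two intervals; Inf when
#' the chromosome has no interval in `b`.
#'
#' @param a,b interval tables.
#' @return numeric vector parallel to rows of `a`.
#' @export
iv_nearest_distance <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  out <- rep(Inf, nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    d <- IRanges::distanceToNearest(.ir(a[ia, , drop = FALSE]), .ir(bb))
    qh <- S4Vectors::queryHits(d)
    out[ia[qh]] <- S4Vectors::mcols(d)$distance
  }
  out
}

#' Reciprocal overlap test
#'
#' For each row of `a`, TRUE if some interval of `b` overlaps it with
#' overlap/len(a) >= frac AND overlap/len(b) >= frac.
#'
#' @param a,b interval tables.
#' @param frac required reciprocal overlap fraction.
#' @return logical vector parallel to rows of `a`.
#' @export
iv_reciprocal_overlap <- function(a, b, frac = 0.9) {
  if (nrow(a) == 0) return(logical(0))
  out <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    ra <- .ir(a[ia, , drop = FALSE]); rb <- .ir(bb)
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ra[qi], rb[si]))
    ok <- ov >= frac * IRanges::width(ra[qi]) & ov >= frac * IRanges::width(rb[si])
    out[ia[unique(qi[ok])]] <- TRUE
  }
  out
}

#' Complement of an interval set within chromosome bounds
#' @param df interval table.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return interval table of uncovered regions.
#' @export
iv_complement <- function(df, chrom_sizes) {
  full <- interval_df(chrom = names(chrom_sizes), start = 0L,
                      end = as.integer(chrom_sizes))
  iv_subtract(full, df)
}

# -- small sequence helpers ---------------------------------------------------

#' Reverse complement of a DNA string
#' @param s character scalar (ACGTN alphabet).
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                       collapse = ""))
}

# 0-based half-open substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)
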