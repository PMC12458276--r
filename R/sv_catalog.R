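# Structural-variant cataloguing: size/chromosome/exclusion filtering,
# repeat-content classification into candidate LINE-1 and SINEC loci, and
# filtered SNV extraction for divergence calibration.

#' Default allowed chromosome set (autosomes plus optionally chrX)
#' @param include_chrX include the X chromosome.
#' @param n_autosomes number of autosomes.
#' @return character vector of chromosome names.
#' @export
allowed_chroms <- function(include_chrX = TRUE, n_autosomes = 38L) {
  c(paste0("chr", seq_len(n_autosomes)), if (include_chrX) "chrX")
}

#' Filter raw structural variant calls
#'
#' Retains SVs of at least `min_len` bp, on allowed chromosomes, with query
#' and target on the same chromosome name, and farther than `window` bp
#' (edge distance, inclusive at `window`) from every exclusion interval in
#' either genome.
#'
#' @param svs SV call table (paftools_tsv schema plus `len`).
#' @param target_exclusions,query_exclusions exclusion interval tables for
#'   the two genomes.
#' @param chroms allowed chromosome names.
#' @param min_len minimum SV size in bp.
#' @param window exclusion window in bp.
#' @return the retained subset of `svs`.
#' @export
filter_svs <- function(svs, target_exclusions = interval_df(),
                       query_exclusions = interval_df(),
                       chroms = allowed_chroms(), min_len = 50L,
                       window = 100L) {
  if (nrow(svs) == 0) return(svs)
  keep <- svs$len >= min_len &
    svs$target_chrom %in% chroms &
    svs$query_chrom == svs$target_chrom
  tiv <- .sv_footprint(svs, "target")
  qiv <- .sv_footprint(svs, "query")
  dt <- iv_nearest_distance(tiv, target_exclusions)
  dq <- iv_nearest_distance(qiv, query_exclusions)
  keep <- keep & dt > window & dq > window
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# interval footprint of an SV in one genome; zero-width junctions become
# 1 bp points for distance computations
.sv_footprint <- function(svs, side = c("target", "query")) {
  side <- match.arg(side)
  ch <- svs[[paste0(side, "_chrom")]]
  st <- svs[[paste0(side, "_start")]]
  en <- svs[[paste0(side, "_end")]]
  en <- pmax(en, st + 1L)
  data.frame(chrom = ch, start = st, end = en, stringsAsFactors = FALSE)
}

#' Classify the repeat content of SV calls
#'
#' Computes, per SV, the fraction of the filled-side interval covered by
#' merged annotations of each element class, and assigns LINE1 or SINEC when
#' the fraction reaches `min_frac`. HAL-family LINEs never count toward
#' LINE1.
#'
#' @param svs SV call table (insertions classified on the query side,
#'   deletions on the target side, i.e. the genome carrying the element).
#' @param annotations annotation table of the filled genome.
#' @param min_frac minimum covered fraction.
#' @return `svs` with columns element_class ("LINE1", "SINEC" or "other") and
#'   repeat_fraction appended.
#' @export
classify_repeat_content <- function(svs, annotations, min_frac = 0.7) {
  if (nrow(svs) == 0) {
    svs$element_class <- character(0); svs$repeat_fraction <- numeric(0)
    return(svs)
  }
  if (any(svs$len <= 0)) stop("zero-length SV")
  side <- ifelse(svs$kind == "insertion", "query", "target")
  iv <- .sv_footprint(svs, "query")
  ivt <- .sv_footprint(svs, "target")
  iv[side == "target", ] <- ivt[side == "target", ]
  sine_ann <- annotations[grepl("^SINE", annotations$repeat_class), , drop = FALSE]
  line_ann <- annotations[grepl("^LINE", annotations$repeat_class) &
                            !grepl("^HAL", annotations$subfamily), , drop = FALSE]
  sv_len <- iv$end - iv$start
  f_sine <- iv_covered_bp(iv, sine_ann) / sv_len
  f_line <- iv_covered_bp(iv, line_ann) / sv_len
  cls <- rep("other", nrow(svs))
  cls[f_sine >= min_frac & f_sine >= f_line] <- "SINEC"
  cls[f_line >= min_frac & f_line > f_sine] <- "LINE1"
  svs$element_class <- cls
  svs$repeat_fraction <- pmax(f_sine, f_line)
  svs
}

#' Filtered SNV count and aligned length
#'
#' Subtracts low-complexity/exclusion regions from the aligned single-contig
#' regions of the target genome, then counts SNVs falling inside the
#' remaining intervals.
#'
#' @param snvs SNV table (chrom, pos in target coordinates).
#' @param aligned_regions interval table of single-contig aligned regions on
#'   the target.
#' @param low_complexity interval table subtracted from the aligned regions
#'   (target-genome exclusions only).
#' @param chroms chromosomes to include (default: all present).
#' @return list with snv_count and aligned_bp.
#' @export
extract_snvs <- function(snvs, aligned_regions,
                         low_complexity = interval_df(), chroms = NULL) {
  if (!is.null(chroms)) {
    aligned_regions <- aligned_regions[aligned_regions$chrom %in% chroms, ,
                                       drop = FALSE]
    snvs <- snvs[snvs$chrom %in% chroms, , drop = FALSE]
  }
  remain <- iv_subtract(aligned_regions, low_complexity)
  aligned_bp <- iv_total_len(remain)
  if (nrow(snvs) == 0) return(list(snv_count = 0L, aligned_bp = aligned_bp))
  pts <- interval_df(chrom = snvs$chrom, start = snvs$pos, end = snvs$pos + 1L)
  inside <- iv_covered_bp(pts, remain) > 0
  list(snv_count = sum(inside), aligned_bp = aligned_bp)
}
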