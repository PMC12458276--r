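# Readers and writers. Everything is normalized to 0-based half-open
# coordinates at the boundary; RepeatMasker .out (1-based inclusive) and VCF
# (1-based) are converted on read and re-converted on write.

#' Read repeat annotations
#'
#' Parses repeat annotations from RepeatMasker `.out` files or BED6 into a
#' normalized annotation table.
#'
#' @param path file path.
#' @param dialect `"rm_out"` (RepeatMasker .out, 1-based inclusive, strand "C"
#'   for minus) or `"bed6"` (name column = subfamily; class defaults from the
#'   subfamily prefix).
#' @return data.frame with columns chrom, start, end, strand, repeat_class,
#'   subfamily, divergence_pct (0-based half-open coordinates).
#' @export
read_repeat_annotation <- function(path, dialect = c("rm_out", "bed6")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "bed6") {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(.empty_annotation())
    fields <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(fields, length, 1L) < 6)
    if (length(bad)) stop("malformed bed6 line ", bad[1], " in ", path)
    f <- do.call(rbind, fields)
    ann <- data.frame(chrom = f[, 1], start = as.integer(f[, 2]),
                      end = as.integer(f[, 3]), strand = f[, 6],
                      repeat_class = .class_from_subfamily(f[, 4]),
                      subfamily = f[, 4], divergence_pct = NA_real_,
                      stringsAsFactors = FALSE)
    validate_intervals(ann)
    return(ann)
  }
  # rm_out: skip the two header lines plus the blank separator
  keep <- which(!grepl("^\\s*$", lines) &
                  !grepl("^\\s*(SW|score)\\b", lines))
  if (length(keep) == 0) return(.empty_annotation())
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n <- vapply(fields, length, 1L)
  bad <- which(n < 13)
  if (length(bad)) stop("malformed rm_out line ", keep[bad[1]], " in ", path)
  f <- do.call(rbind, lapply(fields, `[`, 1:13))
  begin <- suppressWarnings(as.integer(f[, 6]))
  end <- suppressWarnings(as.integer(f[, 7]))
  if (any(is.na(begin)) || any(is.na(end)))
    stop("malformed rm_out coordinates at line ",
         keep[which(is.na(begin) | is.na(end))[1]], " in ", path)
  strand <- ifelse(f[, 9] == "C", "-", f[, 9])
  ann <- data.frame(chrom = f[, 5], start = begin - 1L, end = end,
                    strand = strand, repeat_class = f[, 11], subfamily = f[, 10],
                    divergence_pct = suppressWarnings(as.numeric(f[, 2])),
                    stringsAsFactors = FALSE)
  validate_intervals(ann)
  ann
}

.empty_annotation <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), repeat_class = character(),
             subfamily = character(), divergence_pct = numeric(),
             stringsAsFactors = FALSE)
}

.class_from_subfamily <- function(subfamily) {
  ifelse(grepl("^L1", subfamily), "LINE/L1",
         ifelse(grepl("^SINEC", subfamily), "SINE/tRNA-Lys",
                ifelse(grepl("^HAL", subfamily), "LINE/L1-HAL", "Unknown")))
}

#' Write repeat annotations
#'
#' @param ann annotation table as returned by [read_repeat_annotation()].
#' @param path output file.
#' @param dialect `"rm_out"` or `"bed6"`.
#' @return invisibly, `path`.
#' @export
write_repeat_annotation <- function(ann, path, dialect = c("rm_out", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom, ann$start, ann$end,
                     ann$subfamily, ann$strand)
    writeLines(lines, path)
    return(invisible(path))
  }
  header <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin    end   (left) repeat    class/family  begin  end    (left)  ID",
    "")
  div <- ifelse(is.na(ann$divergence_pct), 0, ann$divergence_pct)
  lines <- sprintf("  225 %5.1f  0.0  0.0  %s %8d %8d (0) %s %s %s  1 %d (0) %d",
                   div, ann$chrom, ann$start + 1L, ann$end,
                   ifelse(ann$strand == "-", "C", "+"), ann$subfamily,
                   ann$repeat_class, ann$end - ann$start, seq_len(nrow(ann)))
  writeLines(c(header, lines), path)
  invisible(path)
}

# -- variant calls ------------------------------------------------------------

.paftools_cols <- c("target_chrom", "target_start", "target_end", "query_chrom",
                    "query_start", "query_end", "kind", "seq")

#' Read pairwise variant calls
#'
#' Separates single-base substitutions (SNVs) from structural variants of at
#' least `min_sv_len` bases. Indels shorter than `min_sv_len` are neither SNV
#' nor SV; they are retained in the `raw` element but excluded downstream.
#'
#' @param path file path.
#' @param dialect `"paftools_tsv"` (the package's 8-column dialect: target
#'   chrom/start/end, query chrom/start/end, kind in snv/insertion/deletion,
#'   seq; for SNVs seq is "REF>ALT") or `"vcf"` (VCF 4.x with full ALT
#'   sequences; requires the vcfR package).
#' @param sample_id sample carrying the query genome.
#' @param min_sv_len minimum structural variant size in bp.
#' @return list with elements `svs` (insertion/deletion calls >= min_sv_len),
#'   `snvs` (chrom, pos, ref, alt on the target), `raw` (all parsed records)
#'   and `n_rejected` (insertions lacking sequence).
#' @export
read_variant_calls <- function(path, dialect = c("paftools_tsv", "vcf"),
                               sample_id = NA_character_, min_sv_len = 50L) {
  dialect <- match.arg(dialect)
  if (dialect == "paftools_tsv") {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "integer", "integer",
                                            "character", "integer", "integer",
                                            "character", "character"),
                             stringsAsFactors = FALSE)
    if (!identical(names(raw), .paftools_cols))
      stop("paftools_tsv header mismatch in ", path)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("the vcf dialect requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    pos <- as.integer(fix[, "POS"]) - 1L
    kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv",
                   ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
    # VCF indels carry the shared anchor base; strip it
    seq <- ifelse(kind == "insertion", substring(alt, 2),
                  ifelse(kind == "deletion", substring(ref, 2),
                         paste0(ref, ">", alt)))
    tstart <- ifelse(kind == "snv", pos, pos + 1L)
    tend <- ifelse(kind == "deletion", tstart + nchar(seq),
                   ifelse(kind == "snv", pos + 1L, tstart))
    raw <- data.frame(target_chrom = fix[, "CHROM"],
                      target_start = as.integer(tstart),
                      target_end = as.integer(tend),
                      query_chrom = fix[, "CHROM"], query_start = NA_integer_,
                      query_end = NA_integer_, kind = kind, seq = seq,
                      stringsAsFactors = FALSE)
  }
  raw$sample_id <- sample_id
  is_ins <- raw$kind == "insertion"
  n_rejected <- sum(is_ins & !nzchar(raw$seq))
  if (n_rejected > 0) {
    warning(n_rejected, " insertion record(s) lacking sequence rejected")
    raw <- raw[!(is_ins & !nzchar(raw$seq)), , drop = FALSE]
  }
  raw$len <- ifelse(raw$kind == "snv", 1L, nchar(raw$seq))
  svs <- raw[raw$kind %in% c("insertion", "deletion") & raw$len >= min_sv_len, ,
             drop = FALSE]
  snv_raw <- raw[raw$kind == "snv", , drop = FALSE]
  ra <- strsplit(snv_raw$seq, ">", fixed = TRUE)
  snvs <- data.frame(chrom = snv_raw$target_chrom, pos = snv_raw$target_start,
                     ref = vapply(ra, `[`, "", 1),
                     alt = vapply(ra, `[`, "", 2),
                     stringsAsFactors = FALSE)
  rownames(svs) <- rownames(snvs) <- NULL
  list(svs = svs, snvs = snvs, raw = raw, n_rejected = n_rejected)
}

#' Write variant calls in the paftools_tsv dialect
#' @param calls data.frame with the 8 paftools_tsv columns (extras dropped).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_variant_calls <- function(calls, path) {
  df <- calls[, .paftools_cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- locus tables -------------------------------------------------------------

.locus_cols <- c("locus_id", "sample_id", "direction", "chrom", "start", "end",
                 "target_chrom", "target_pos", "element_class", "subfamily",
                 "orientation", "tsd_seq", "tsd_len", "polya_len", "polya_gap",
                 "ts_del_len", "en_site", "stringent_class", "relaxed_class",
                 "insert_len", "non_tsd_bp", "flank_used", "qc_pass", "qc_reason")

.locus_classes <- c(locus_id = "character", sample_id = "character",
                    direction = "character", chrom = "character",
                    start = "integer", end = "integer",
                    target_chrom = "character", target_pos = "integer",
                    element_class = "character", subfamily = "character",
                    orientation = "character", tsd_seq = "character",
                    tsd_len = "integer", polya_len = "integer",
                    polya_gap = "integer", ts_del_len = "integer",
                    en_site = "character", stringent_class = "character",
                    relaxed_class = "character", insert_len = "integer",
                    non_tsd_bp = "integer", flank_used = "integer",
                    qc_pass = "logical", qc_reason = "character")

#' Canonical empty locus table
#' @return zero-row data.frame with the documented locus columns.
#' @export
empty_locus_table <- function() {
  df <- lapply(.locus_classes, function(cl) vector(cl, 0))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Write a locus table
#'
#' Tab-separated with a fixed, documented column order; round-trips losslessly
#' through [read_locus_table()]. Missing strings (e.g. no TSD) are written as
#' empty fields.
#'
#' @param loci locus table (columns as in [empty_locus_table()]; missing
#'   columns are filled with NA).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_locus_table <- function(loci, path) {
  for (cl in .locus_cols) if (is.null(loci[[cl]])) loci[[cl]] <- NA
  df <- loci[, .locus_cols, drop = FALSE]
  for (cl in names(df)) if (is.character(df[[cl]])) df[[cl]][is.na(df[[cl]])] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a locus table written by [write_locus_table()]
#' @param path file path.
#' @return locus data.frame.
#' @export
read_locus_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = unname(.locus_classes),
                          stringsAsFactors = FALSE, na.strings = "NA")
  chr_cols <- names(.locus_classes)[.locus_classes == "character"]
  for (cl in chr_cols) df[[cl]][is.na(df[[cl]])] <- ""
  df
}

# -- FASTA / BED --------------------------------------------------------------

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read BED3 into an interval table
#' @param path BED file.
#' @return interval table (chrom, start, end).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(interval_df())
  f <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(f, length, 1L) < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  m <- do.call(rbind, lapply(f, `[`, 1:3))
  interval_df(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]))
}

#' Write an interval table as BED3
#' @param df interval table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}
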