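# End-to-end orchestration: one pairwise comparison (catalog -> refine ->
# hallmarks), the full cohort analysis (merge -> presence matrix -> tree ->
# rates -> transductions), and truth-recovery evaluation against a simulated
# bundle.

#' Pipeline configuration
#'
#' All thresholds of the filter cascade as named constants.
#'
#' @param ... overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_sv_len = 50L, repeat_frac = 0.7, exclusion_window = 100L,
    flanks = c(1000L, 500L, 250L, 125L), max_shift = 150L,
    min_insert_len = 50L, min_non_tsd = 30L,
    l1_min_frac = 0.7, l1_min_tsd = 10L,
    min_tsd_hc = 10L, min_polya = 10L, max_polya_gap = 5L,
    relaxed_min_tsd = 7L, relaxed_window = 15L, relaxed_min_a = 10L,
    relaxed_range = 30L, min_segment = 20L,
    merge_gap = 100L, include_chrX_cohort = FALSE,
    bootstrap_replicates = 1000L, seed = 1L,
    mu = 4.5e-9, mu_low = 2.6e-9, mu_high = 7.1e-9,
    td_min_len = 25L, td_min_unmasked = 25L, td_min_identity = 0.95,
    td_min_match = 25L, td_self_exclusion = 10000L, td_max_hits = 50L,
    td_max_per_locus = 5L, td_parent_window = 50L, td_merge_gap = 100L,
    tsd_max_mismatch = 0L)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown pipeline option: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run one pairwise comparison
#'
#' Catalog, refine, QC and hallmark-classify all dimorphic candidate loci of
#' one query-vs-target comparison, in both directions (insertions present in
#' the query and absent from the target, and vice versa), and extract
#' filtered SNV counts for divergence calibration.
#'
#' @param bundle a `cohort_bundle`.
#' @param query,target sample names.
#' @param calls optional call table (default: exact calls from the bundle).
#' @param cfg a [pipeline_config()].
#' @param jitter breakpoint jitter passed to the call emitter when `calls` is
#'   NULL.
#' @return object of class `pair_report`: locus table, SNV statistics,
#'   per-class counts, and the SINEC:SNV ratio.
#' @export
run_pair <- function(bundle, query, target = bundle$outgroup, calls = NULL,
                     cfg = pipeline_config(), jitter = 0L) {
  if (is.null(calls)) calls <- pair_variant_calls(bundle, query, target, jitter)
  chroms <- intersect(names(bundle$chrom_lengths), allowed_chroms())
  autosomes <- setdiff(chroms, "chrX")
  svs <- calls[calls$kind %in% c("insertion", "deletion") &
                 calls$len >= cfg$min_sv_len, , drop = FALSE]
  n_raw <- nrow(svs)
  svs <- filter_svs(svs, bundle$exclusions[[target]],
                    bundle$exclusions[[query]], chroms,
                    min_len = cfg$min_sv_len, window = cfg$exclusion_window)
  n_filtered <- nrow(svs)
  ins <- classify_repeat_content(svs[svs$kind == "insertion", , drop = FALSE],
                                 bundle$annotations[[query]], cfg$repeat_frac)
  del <- classify_repeat_content(svs[svs$kind == "deletion", , drop = FALSE],
                                 bundle$annotations[[target]], cfg$repeat_frac)
  cand <- rbind(ins, del)
  cand <- cand[cand$element_class != "other", , drop = FALSE]
  n_candidates <- nrow(cand)
  loci <- list()
  for (i in seq_len(nrow(cand))) {
    row <- .process_locus(cand[i, ], bundle, query, target, cfg)
    if (!is.null(row)) loci[[length(loci) + 1]] <- row
  }
  loci <- if (length(loci)) do.call(rbind, loci) else empty_locus_table()
  rownames(loci) <- NULL
  snv_stats <- extract_snvs(
    read_snv_table(calls), pair_homologous_regions(bundle, query, target),
    low_complexity = bundle$exclusions[[target]], chroms = autosomes)
  ok <- loci$qc_pass & loci$chrom %in% autosomes
  n_sinec <- sum(ok & loci$element_class == "SINEC")
  structure(list(
    query = query, target = target, loci = loci,
    snv_count = snv_stats$snv_count, aligned_bp = snv_stats$aligned_bp,
    cascade = c(raw = n_raw, filtered = n_filtered,
                candidates = n_candidates, refined = sum(loci$qc_pass)),
    sinec_snv_ratio = if (snv_stats$snv_count > 0)
      n_sinec / snv_stats$snv_count else NA_real_),
    class = "pair_report")
}

#' Extract the SNV table from a call table
#' @param calls call table in the paftools_tsv schema.
#' @return data.frame chrom, pos, ref, alt (target coordinates).
#' @export
read_snv_table <- function(calls) {
  s <- calls[calls$kind == "snv", , drop = FALSE]
  ra <- strsplit(s$seq, ">", fixed = TRUE)
  data.frame(chrom = s$target_chrom, pos = s$target_start,
             ref = vapply(ra, `[`, "", 1), alt = vapply(ra, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' @export
print.pair_report <- function(x, ...) {
  ok <- x$loci$qc_pass
  cat(sprintf("pair_report %s vs %s: %d loci pass QC (%d SINEC, %d LINE1)\n",
              x$query, x$target, sum(ok),
              sum(ok & x$loci$element_class == "SINEC"),
              sum(ok & x$loci$element_class == "LINE1")))
  cat(sprintf("  SNVs: %d in %d aligned bp; SINEC:SNV ratio %.4g\n",
              x$snv_count, x$aligned_bp, x$sinec_snv_ratio))
  invisible(x)
}

.process_locus <- function(cand, bundle, query, target, cfg) {
  if (cand$kind == "insertion") {
    filled_sample <- query; empty_sample <- target
    filled_pos <- cand$query_start; empty_pos <- cand$target_start
    direction <- "query"
  } else {
    filled_sample <- target; empty_sample <- query
    filled_pos <- cand$target_start; empty_pos <- cand$query_start
    direction <- "target"
  }
  ch <- cand$target_chrom
  filled_seq <- bundle$genomes[[filled_sample]][[ch]]
  empty_seq <- bundle$genomes[[empty_sample]][[ch]]
  ref <- refine_locus(filled_seq, empty_seq, filled_pos, empty_pos, cand$len,
                      flanks = cfg$flanks, max_shift = cfg$max_shift,
                      min_insert_len = cfg$min_insert_len,
                      min_non_tsd = cfg$min_non_tsd,
                      tsd_max_mismatch = cfg$tsd_max_mismatch)
  ann <- bundle$annotations[[filled_sample]]
  if (ref$qc_pass && cand$element_class == "LINE1")
    ref <- apply_line1_fp_filters(ref, ann, ch, cfg$l1_min_frac, cfg$l1_min_tsd)
  orientation <- NA_character_
  polya <- list(polya_len = 0L, polya_gap = NA_integer_)
  en <- NA_character_; subfam <- ""
  s_class <- r_class <- NA_character_
  if (ref$qc_pass) {
    orientation <- detect_orientation(ann, ch, ref$insert_start,
                                      ref$insert_end, cfg$min_segment)
    if (orientation == "removed") {
      ref$qc_pass <- FALSE; ref$qc_reason <- "no_orientation_segment"
    }
  }
  if (ref$qc_pass) {
    if (orientation %in% c("+", "-"))
      polya <- detect_polya(ref$insert_seq, orientation,
                            cfg$max_polya_gap, cfg$min_polya)
    en <- extract_en_site(filled_seq, ref$insert_start, ref$insert_end,
                          ref$tsd_len, orientation, cfg$min_tsd_hc)
    subfam <- assign_subfamily(ann, ch, ref$insert_start, ref$insert_end,
                               cfg$min_segment)
    s_class <- classify_hallmarks(ref$tsd_len, polya$polya_len,
                                  polya$polya_gap, orientation,
                                  ref$insert_seq, "stringent",
                                  cfg$min_tsd_hc, cfg$min_polya,
                                  cfg$max_polya_gap)
    r_class <- classify_hallmarks(ref$tsd_len, polya$polya_len,
                                  polya$polya_gap, orientation,
                                  ref$insert_seq, "relaxed",
                                  relaxed_min_tsd = cfg$relaxed_min_tsd,
                                  relaxed_window = cfg$relaxed_window,
                                  relaxed_min_a = cfg$relaxed_min_a,
                                  relaxed_range = cfg$relaxed_range)
  }
  target_pos <- if (direction == "query") ref$refined_junction else ref$insert_start
  if (is.na(target_pos)) target_pos <- cand$target_start
  data.frame(
    locus_id = sprintf("%s_%s_%s_%d", query, target, ch, cand$target_start),
    sample_id = filled_sample, direction = direction, chrom = ch,
    start = ref$insert_start, end = ref$insert_end,
    target_chrom = ch, target_pos = as.integer(target_pos),
    element_class = cand$element_class, subfamily = subfam,
    orientation = if (is.na(orientation)) "" else orientation,
    tsd_seq = ref$tsd_seq, tsd_len = ref$tsd_len,
    polya_len = polya$polya_len, polya_gap = polya$polya_gap,
    ts_del_len = ref$ts_del_len,
    en_site = if (is.na(en)) "" else en,
    stringent_class = if (is.na(s_class)) "" else s_class,
    relaxed_class = if (is.na(r_class)) "" else r_class,
    insert_len = ref$insert_len, non_tsd_bp = ref$non_tsd_bp,
    flank_used = ref$flank_used, qc_pass = ref$qc_pass,
    qc_reason = ref$qc_reason,
    event_id = if (is.null(cand$event_id)) NA_character_ else cand$event_id,
    insert_seq = ref$insert_seq,
    stringsAsFactors = FALSE)
}

#' Run the full cohort analysis
#'
#' All samples are compared against the outgroup; per-pair loci are filtered
#' to callable autosomal regions, merged across samples, summarized as
#' presence/absence matrices per element class, used to build bootstrapped
#' neighbor-joining trees with branch assignment, converted into per-branch
#' retrotransposition rate estimates, and mined for 3' transductions.
#'
#' @param bundle a `cohort_bundle`.
#' @param cfg a [pipeline_config()].
#' @param gwolf_via sample whose comparison contributes the outgroup-branch
#'   counts (avoids counting the outgroup once per comparison); default the
#'   first non-outgroup sample.
#' @return object of class `retrodiff_cohort`.
#' @export
run_cohort <- function(bundle, cfg = pipeline_config(), gwolf_via = NULL) {
  og <- bundle$outgroup
  queries <- setdiff(bundle$samples, og)
  if (is.null(gwolf_via)) gwolf_via <- queries[1]
  pairs <- lapply(queries, function(q) run_pair(bundle, q, og, cfg = cfg))
  names(pairs) <- queries
  callable <- compute_callable(
    lapply(queries, function(q) pair_aligned_regions(bundle, og)),
    bundle$exclusions[[og]])
  chroms <- if (cfg$include_chrX_cohort)
    intersect(names(bundle$chrom_lengths), allowed_chroms())
  else setdiff(names(bundle$chrom_lengths), "chrX")
  all_loci <- do.call(rbind, lapply(queries, function(q) {
    l <- pairs[[q]]$loci
    l <- l[l$qc_pass & l$chrom %in% chroms, , drop = FALSE]
    if (nrow(l) == 0) return(NULL)
    data.frame(chrom = l$target_chrom, pos = l$target_pos,
               carrier = ifelse(l$direction == "query", q, og),
               comparison = q, direction = l$direction,
               element_class = l$element_class,
               locus_id = l$locus_id, tsd_len = l$tsd_len,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_loci))
    all_loci <- data.frame(chrom = character(), pos = integer(),
                           carrier = character(), comparison = character(),
                           direction = character(), element_class = character(),
                           locus_id = character(), tsd_len = integer(),
                           stringsAsFactors = FALSE)
  pts <- interval_df(all_loci$chrom, all_loci$pos,
                     pmin(all_loci$pos + 1L, all_loci$pos + 1L))
  in_callable <- if (nrow(all_loci)) iv_covered_bp(pts, callable) > 0 else logical(0)
  all_loci <- all_loci[in_callable, , drop = FALSE]
  share <- list(); trees <- list(); branches <- list()
  for (cls in c("SINEC", "LINE1")) {
    sub <- all_loci[all_loci$element_class == cls, , drop = FALSE]
    mg <- merge_loci(sub, cfg$merge_gap, samples = bundle$samples,
                     outgroup = og)
    pm <- presence_matrix(mg$merged, bundle$samples)
    share[[cls]] <- list(merged = mg, matrix = pm,
                         profile = sharing_profile(pm))
    if (nrow(pm) >= 3) {
      bs <- bootstrap_support(pm, cfg$bootstrap_replicates, cfg$seed)
      trees[[cls]] <- bs
      branches[[cls]] <- assign_loci_to_branches(pm, bs$tree)
    }
  }
  rates <- cohort_rates(pairs, cfg, gwolf_via = gwolf_via, chroms = chroms)
  td <- cohort_transductions(bundle, pairs, cfg)
  structure(list(outgroup = og, pairs = pairs, callable = callable,
                 loci = all_loci, share = share, trees = trees,
                 branches = branches, rates = rates, transductions = td,
                 config = cfg),
            class = "retrodiff_cohort")
}

#' Per-branch and cohort-average retrotransposition rates
#'
#' Each query comparison contributes its query-side insertion counts (the
#' sample branch); the outgroup branch is counted once, via the target-side
#' counts of the `gwolf_via` comparison. The cohort average is the mean of
#' the per-branch denominators.
#'
#' @param pairs list of `pair_report`s.
#' @param cfg pipeline config (mu and bounds).
#' @param gwolf_via comparison used for the outgroup branch.
#' @param chroms chromosomes counted (autosomes by default).
#' @return data.frame of per-branch estimates plus rows `average`; columns
#'   include generations, counts, denominators and mutation-rate bounds for
#'   all loci and for the stringent (TSD >= 10) subset.
#' @export
cohort_rates <- function(pairs, cfg = pipeline_config(), gwolf_via = NULL,
                         chroms = NULL) {
  if (is.null(gwolf_via)) gwolf_via <- names(pairs)[1]
  rows <- list()
  branch_row <- function(name, rep, direction) {
    l <- rep$loci
    if (!is.null(chroms)) l <- l[l$chrom %in% chroms, , drop = FALSE]
    l <- l[l$qc_pass & l$direction == direction, , drop = FALSE]
    gen <- genome_divergence(rep$snv_count, rep$aligned_bp, cfg$mu)
    mk <- function(cnt) if (cnt > 0) gen / cnt else NA_real_
    n_s <- sum(l$element_class == "SINEC")
    n_l <- sum(l$element_class == "LINE1")
    n_s_hc <- sum(l$element_class == "SINEC" & l$tsd_len >= cfg$min_tsd_hc)
    n_l_hc <- sum(l$element_class == "LINE1" & l$tsd_len >= cfg$min_tsd_hc)
    data.frame(branch = name, generations = gen, snv_count = rep$snv_count,
               aligned_bp = rep$aligned_bp,
               sinec_count = n_s, line1_count = n_l,
               sinec_count_hc = n_s_hc, line1_count_hc = n_l_hc,
               sinec_N = mk(n_s), line1_N = mk(n_l),
               sinec_N_hc = mk(n_s_hc), line1_N_hc = mk(n_l_hc),
               stringsAsFactors = FALSE)
  }
  for (q in names(pairs)) rows[[q]] <- branch_row(q, pairs[[q]], "query")
  rows[["outgroup"]] <- branch_row(pairs[[gwolf_via]]$target,
                                   pairs[[gwolf_via]], "target")
  df <- do.call(rbind, rows)
  avg <- df[1, ]
  avg$branch <- "average"
  for (cl in setdiff(names(df), "branch")) avg[[cl]] <- mean(df[[cl]], na.rm = TRUE)
  df <- rbind(df, avg)
  for (cl in c("sinec_N", "line1_N", "sinec_N_hc", "line1_N_hc")) {
    df[[paste0(cl, "_low_mu")]] <- rescale_rate_bounds(df[[cl]], cfg$mu, cfg$mu_low)
    df[[paste0(cl, "_high_mu")]] <- rescale_rate_bounds(df[[cl]], cfg$mu, cfg$mu_high)
  }
  rownames(df) <- NULL
  df
}

#' Mine 3' transductions across the cohort
#'
#' @param bundle cohort bundle.
#' @param pairs list of `pair_report`s from the outgroup comparisons.
#' @param cfg pipeline config.
#' @return list with `hits`, `clusters`, and per-sample `summary`
#'   (eligible candidates and mapped loci).
#' @export
cohort_transductions <- function(bundle, pairs, cfg = pipeline_config()) {
  og <- bundle$outgroup
  og_genome <- bundle$genomes[[og]]
  chroms <- intersect(names(bundle$chrom_lengths), allowed_chroms())
  all_hits <- list(); summ <- list()
  for (q in names(pairs)) {
    l <- pairs[[q]]$loci
    l <- l[l$qc_pass & l$element_class == "LINE1" &
             l$orientation %in% c("+", "-"), , drop = FALSE]
    n_eligible <- 0L; n_mapped <- 0L
    for (i in seq_len(nrow(l))) {
      filled_sample <- l$sample_id[i]
      cand <- extract_transduction_candidate(
        bundle$genomes[[filled_sample]][[l$chrom[i]]], l$chrom[i],
        l$start[i], l$end[i], l$orientation[i],
        bundle$annotations[[filled_sample]], cfg$td_min_len)
      cand <- mask_low_complexity(cand, min_unmasked = cfg$td_min_unmasked)
      if (is.null(cand)) next
      n_eligible <- n_eligible + 1L
      hits <- search_genome(
        cand, og_genome, self_chrom = l$target_chrom[i],
        self_start = l$target_pos[i], self_end = l$target_pos[i] + 1L,
        chroms = chroms, min_identity = cfg$td_min_identity,
        min_match = cfg$td_min_match, self_exclusion = cfg$td_self_exclusion,
        max_hits = cfg$td_max_hits,
        min_unmasked_aligned = cfg$td_min_unmasked)
      if (nrow(hits) == 0 || nrow(hits) > cfg$td_max_per_locus) next
      hits$sample <- l$sample_id[i]
      hits$comparison <- q
      hits$locus_id <- l$locus_id[i]
      hits$event_id <- l$event_id[i]
      n_mapped <- n_mapped + 1L
      all_hits[[length(all_hits) + 1]] <- hits
    }
    summ[[q]] <- data.frame(comparison = q, eligible = n_eligible,
                            mapped = n_mapped, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits))
    hits <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       identity = numeric(), match_bp = integer(),
                       sample = character(), comparison = character(),
                       locus_id = character(), event_id = character(),
                       stringsAsFactors = FALSE)
  src <- classify_sources(hits, bundle$annotations[[og]],
                          cfg$td_parent_window, cfg$td_merge_gap)
  list(hits = src$hits, clusters = src$clusters,
       summary = do.call(rbind, summ))
}

#' @export
print.retrodiff_cohort <- function(x, ...) {
  cat("retrodiff_cohort:", length(x$pairs), "comparisons vs", x$outgroup, "\n")
  for (cls in names(x$share)) {
    pr <- x$share[[cls]]$profile
    cat(sprintf("  %s: %d cohort loci, %d singletons (%.1f%%)\n", cls,
                pr$total, pr$singletons, pr$singleton_pct))
  }
  avg <- x$rates[x$rates$branch == "average", ]
  if (nrow(avg))
    cat(sprintf("  average rates: SINEC 1/%.1f (stringent 1/%.1f), LINE1 1/%.1f (stringent 1/%.1f)\n",
                avg$sinec_N, avg$sinec_N_hc, avg$line1_N, avg$line1_N_hc))
  invisible(x)
}

#' Evaluate pipeline recovery against simulator truth
#'
#' For every (event, comparison) instance where an implanted insertion
#' distinguishes the two genomes and lies outside exclusion windows, checks
#' whether the pipeline recovered the locus with exact TSD and poly(A)
#' lengths, and counts confounder internal-deletion loci that leaked through
#' as dimorphic LINE-1 calls.
#'
#' @param bundle cohort bundle.
#' @param pairs list of `pair_report`s (or a `retrodiff_cohort`).
#' @param exclusion_window bp around exclusions considered ineligible.
#' @return list of recovery fractions and counts.
#' @export
evaluate_recovery <- function(bundle, pairs, exclusion_window = 100L) {
  if (inherits(pairs, "retrodiff_cohort")) pairs <- pairs$pairs
  paths <- .paths(bundle$tree)
  truth <- bundle$truth
  excl <- bundle$ancestral_exclusions
  n_inst <- 0L; n_rec <- 0L; n_tsd <- 0L; n_pa <- 0L
  for (q in names(pairs)) {
    rep <- pairs[[q]]
    sym <- c(setdiff(paths[[q]], paths[[rep$target]]),
             setdiff(paths[[rep$target]], paths[[q]]))
    tv <- truth[truth$branch %in% sym & !truth$is_het_in_assembly, ,
                drop = FALSE]
    if (nrow(tv) == 0) next
    pts <- interval_df(tv$chrom, tv$site, tv$site + 1L)
    eligible <- iv_nearest_distance(pts, excl) > exclusion_window
    tv <- tv[eligible, , drop = FALSE]
    loci <- rep$loci[rep$loci$qc_pass, , drop = FALSE]
    for (i in seq_len(nrow(tv))) {
      n_inst <- n_inst + 1L
      hit <- loci[!is.na(loci$event_id) & loci$event_id == tv$event_id[i], ,
                  drop = FALSE]
      if (nrow(hit) == 0) next
      n_rec <- n_rec + 1L
      if (hit$tsd_len[1] == tv$tsd_len[i]) n_tsd <- n_tsd + 1L
      want_pa <- if (tv$polya_len[i] >= 10) tv$polya_len[i] else 0L
      if (hit$polya_len[1] == want_pa) n_pa <- n_pa + 1L
    }
  }
  conf_ids <- bundle$confounders$event_id
  fp <- 0L
  for (q in names(pairs)) {
    l <- pairs[[q]]$loci
    fp <- fp + sum(l$qc_pass & l$element_class == "LINE1" &
                     !is.na(l$event_id) & l$event_id %in% conf_ids)
  }
  list(n_instances = n_inst, recovered = n_rec,
       recovery = if (n_inst) n_rec / n_inst else NaN,
       tsd_exact = if (n_rec) n_tsd / n_rec else NaN,
       polya_exact = if (n_rec) n_pa / n_rec else NaN,
       confounder_fp = fp)
}
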