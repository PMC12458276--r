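# SNV-calibrated retrotransposition rates. Genome divergence in generations
# is SNVcount * 0.5 / (aligned autosomal bp * mutation rate); the per-birth
# insertion rate denominator is generations / insertion count, with bounds
# from the mutation-rate confidence interval (generations scale as 1/mu with
# insertion counts fixed).

#' Generations since genome divergence
#'
#' @param snv_count filtered autosomal SNV count between the pair.
#' @param aligned_bp filtered autosomal aligned length in bp.
#' @param mu per-bp per-generation SNV mutation rate.
#' @return estimated generations separating each lineage from their common
#'   ancestor (the factor 0.5 splits the pairwise differences between the two
#'   lineages).
#' @export
genome_divergence <- function(snv_count, aligned_bp, mu) {
  if (aligned_bp <= 0) stop("aligned_bp must be positive")
  if (mu <= 0) stop("mu must be positive")
  snv_count * 0.5 / (aligned_bp * mu)
}

#' Births-per-insertion denominator
#'
#' @param generations generations since divergence.
#' @param insertion_count dimorphic insertion count on the branch.
#' @return N such that one insertion arises per N births.
#' @export
insertion_rate <- function(generations, insertion_count) {
  if (insertion_count == 0) stop("insertion_count must be positive")
  generations / insertion_count
}

#' Rescale a rate denominator to a mutation-rate bound
#'
#' @param point_N denominator at the point-estimate mutation rate.
#' @param mu point-estimate mutation rate.
#' @param mu_bound bound of the mutation-rate confidence interval.
#' @return denominator implied by the bound (generations scale as 1/mu).
#' @export
rescale_rate_bounds <- function(point_N, mu, mu_bound) {
  if (mu_bound <= 0) stop("mu_bound must be positive")
  point_N * mu / mu_bound
}

#' Rate estimate with mutation-rate bounds
#'
#' @param snv_count,aligned_bp,mu see [genome_divergence()].
#' @param insertion_count insertions on the branch.
#' @param mu_low,mu_high mutation-rate confidence bounds.
#' @return object of class `rate_estimate`.
#' @export
rate_estimate <- function(snv_count, aligned_bp, mu, insertion_count,
                          mu_low = 2.6e-9, mu_high = 7.1e-9) {
  stopifnot(mu_low <= mu, mu <= mu_high)
  gen <- genome_divergence(snv_count, aligned_bp, mu)
  n <- insertion_rate(gen, insertion_count)
  structure(list(snv_count = snv_count, aligned_bp = aligned_bp, mu = mu,
                 generations = gen, insertion_count = insertion_count,
                 births_per_insertion = n,
                 bounds = c(low_mu = rescale_rate_bounds(n, mu, mu_low),
                            high_mu = rescale_rate_bounds(n, mu, mu_high))),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: 1/%.1f births (generations = %.0f, insertions = %d)\n",
              x$births_per_insertion, x$generations, x$insertion_count))
  cat(sprintf("  mutation-rate bounds: 1/%.1f - 1/%.1f\n",
              x$bounds["high_mu"], x$bounds["low_mu"]))
  invisible(x)
}

#' Heterozygous fraction of dimorphic loci
#'
#' A dimorphic locus counts as heterozygous when some deletion call overlaps
#' it with at least `frac` reciprocal overlap (overlap/locus and
#' overlap/deletion both >= frac).
#'
#' @param loci interval table of dimorphic element loci.
#' @param het_deletions interval table of heterozygous deletion calls.
#' @param frac reciprocal overlap fraction.
#' @return list with count and percent (0.1 precision).
#' @export
heterozygous_fraction <- function(loci, het_deletions, frac = 0.9) {
  hit <- iv_reciprocal_overlap(loci, het_deletions, frac)
  list(count = sum(hit),
       percent = round(100 * sum(hit) / max(1L, nrow(loci)), 1))
}

#' Expected pairwise coalescence time
#'
#' @param Ne effective population size.
#' @return expected generations to coalescence of two lineages (2 Ne).
#' @export
expected_pairwise_coalescence <- function(Ne) {
  if (Ne < 0) stop("Ne must be >= 0")
  2 * Ne
}

#' Rescale a published retrotransposition rate to new calibration constants
#'
#' Pedigree rates are direct observations and are returned unchanged;
#' phylogeny-calibrated rates scale linearly in 1/mu; population-model rates
#' scale linearly in Ne.
#'
#' @param published_N published denominator (the N of "1/N births").
#' @param kind "pedigree", "phylogeny" or "population_model".
#' @param old_calib original calibration constant (mu for phylogeny, Ne for
#'   population_model; ignored for pedigree).
#' @param new_calib new calibration constant.
#' @return rescaled denominator.
#' @export
rescale_published_rate <- function(published_N,
                                   kind = c("pedigree", "phylogeny",
                                            "population_model"),
                                   old_calib = NULL, new_calib = NULL) {
  kind <- match.arg(kind)
  if (kind == "pedigree") return(published_N)
  if (is.null(old_calib) || is.null(new_calib))
    stop("old_calib and new_calib required for ", kind)
  switch(kind,
         phylogeny = published_N * old_calib / new_calib,
         population_model = published_N * new_calib / old_calib)
}

#' Round a rate denominator at printed precision
#' @param n denominator.
#' @return denominator rounded half-up to one decimal.
#' @export
round_denominator <- function(n) floor(n * 10 + 0.5) / 10
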