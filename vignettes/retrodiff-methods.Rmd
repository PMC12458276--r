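---
title: "Detecting dimorphic retrotransposons and calibrating their insertion rate"
author: "retrodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dimorphic retrotransposons and calibrating their insertion rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodiff)
```

## The problem

Comparing two genome assemblies of the same species reveals loci where a
retrotransposon — a LINE-1, or a SINE mobilized in trans by LINE-1
machinery — is present in one assembly ("filled site") and absent from the
other ("empty site"). Canine genomes are a striking case: tens of thousands
of SINEC and thousands of LINE-1 insertions differ between any pair of dog
assemblies. From a panel of assemblies aligned to a common outgroup, such
dimorphic loci support three analyses:

1. **Validation.** Genuine insertions by target-primed reverse transcription
   (TPRT) carry hallmarks: a target site duplication (TSD) flanking the
   insert, a 3' poly(A) tail, and an endonuclease cleavage site matching the
   5'-TTTTT/AA consensus nicked by ORF2p.
2. **Phylogenetics.** Presence/absence patterns across samples are two-state
   characters; a neighbor-joining tree built from their p-distances, rooted
   on an all-absent ancestral pseudo-sample, should recover the known sample
   relationships, and each locus can be assigned to the branch on which it
   arose.
3. **Rate calibration.** The number of generations separating each sample
   from the outgroup can be estimated from the SNV count, the aligned
   autosomal length, and a per-generation SNV mutation rate; dividing
   generations by the number of dimorphic insertions on a branch yields the
   per-birth insertion rate denominator N ("one new insertion per N
   births").

retrodiff implements this entire chain, and couples it to a forward cohort
simulator with complete ground truth, so that every stage — breakpoint
refinement, TSD calling, hallmark classification, cross-sample merging, tree
building, rate estimation, transduction tracing — is testable end to end
without multi-gigabase assemblies.

## The generative model behind the simulator

`simulate_cohort()` evolves a random ancestral genome down a fixed rooted
tree whose branch lengths are generation counts. Per branch of length $g$:

* SNVs: $\mathrm{Binomial}(L, \mu g)$ substitutions at distinct ancestral
  positions, with $\mu = 4.5\times10^{-9}$ per bp per generation by default
  (the wolf pedigree point estimate; confidence bounds
  $2.6\times10^{-9}$–$7.1\times10^{-9}$ are carried through the rate
  module).
* Insertions: $\mathrm{Poisson}(g \cdot r)$ events, with
  $r_{\mathrm{SINEC}} = 1/20$ and $r_{\mathrm{LINE1}} = 1/150$ births by
  default, matching the magnitudes estimated for canines.
* Confounders: internal deletions of ancestral LINE-1 copies (which
  masquerade as dimorphic LINE-1 "insertions" in the opposite genome) and
  exclusion regions covering a configurable fraction of the genome.

Each insertion reproduces the TPRT anatomy implemented by
`implant_insertion()`: the `tsd_len` bases following the endonuclease nick
are duplicated so that they flank the inserted block, the block is the
element body (optionally 5'-truncated, optionally carrying a 3' transduced
tail copied from a donor locus) followed by a poly(A) tail, and
minus-orientation blocks are reverse-complemented as a whole. Endonuclease
site preference is modeled by drawing, with probability `en_site_bias`, the
nick position from genomic positions whose context reads TTAAAAA around the
nick (plus strand; the mirrored TTTTTAA context for minus insertions), so
that extracted cleavage sites superimpose on the canonical 5'-TTTTT/AA
motif.

Default hallmark distributions, chosen once as field-plausible values and
configurable in `sim_config()`:

* TSD length: uniform on 5–20 bp (TSDs are typically 7–20 bp).
* poly(A) length: geometric with mean 25 bp.
* LINE-1 5' truncation: full-length with probability 0.25, otherwise the
  retained fraction is uniform (most genomic LINE-1 copies are heavily
  truncated).
* 3' transduction: probability 0.1 per LINE-1, length uniform 50–400 bp,
  with half the donors placed directly downstream of an ancestral
  (outgroup-fixed) LINE-1 so that parent adjacency is testable, and a
  configurable probability of re-using a donor ("hot" source loci).

**Identifiability constraints.** Two deliberate restrictions make ground
truth well defined. First, insertion sites are rejection-sampled so the
junction is unambiguous: the genomic base before the nick must differ from
the last base of the inserted block, and the base following the TSD must
differ from its first base (and an all-one-base TSD must not extend into
either flank). Without this, a fraction of implants admit several equally
valid (breakpoint, TSD) decompositions and "exact recovery" is not a
meaningful target. Second, the element consensus sequences (synthetic: a
200 bp SINEC with a (CT)~n~ tract, a 6 kb LINE-1; both free of homopolymer
runs, starting with G and ending with C) end in a non-A base so the
implanted poly(A) length is the exact run length at the element's 3' end.
Real data violate both assumptions occasionally, which is one reason the
hallmark fractions observed in real cohorts are lower bounds.

`het_sampling_bias` models the haploid-assembly representation of
heterozygous sites: with probability $1 - \mathrm{bias}$ a terminal-branch
insertion is dropped from the emitted assembly (but kept in the truth table,
flagged). The default is 1 — the emitted haploid assembly represents one
sampled lineage, on which the branch's events are by definition present —
and values below 1 emulate the assembly-specific bias against filled
heterozygous SINEC sites reported for one of the published boxer assemblies.

The simulator also knows what it does **not** model: no recombination, no
selection, no nested same-path insertions closer than `min_site_spacing`
(300 bp), no sequencing error, no assembly gaps beyond the exclusion
regions, and SNVs never fall inside younger inserted blocks. Passing the
truth-recovery suite therefore demonstrates correctness of the pipeline's
logic, not robustness to assembly artifacts.

## Breakpoint refinement and TSD calling

Raw pairwise calls locate an insertion only approximately. `refine_locus()`
performs the split alignment that a structural-variant aligner would: the
filled and empty alleles are extracted with 1,000 bp flanks, the left flanks
are compared prefix-wise and the right flanks suffix-wise with +1/−1
identity scores, and the breakpoints maximize the summed flank scores. Two
numerical choices matter:

* **Anchoring.** Each breakpoint is snapped to the end of a ≥20 bp exact
  identity run (candidates are run ends; the score decides among them, ties
  to the leftmost). A raw ±1 score walk drifts past the true junction with
  probability ≈ 1/3 per flank on random sequence; anchoring makes the
  refined junction deterministic and exact on clean data while isolated
  SNVs in the flank merely split the run without moving its end.
* **Right-window anchoring.** The filled window's right edge is located by
  searching for the empty window's terminal 30-mer near its expected
  position, so target site deletions and call-length jitter cannot shear
  the positional suffix comparison.

If the refined junction lies more than 150 bp from the input coordinate, or
either flank fails to anchor (the signature of a second variant inside the
window), the refinement retries with 500, 250 and then 125 bp flanks; it is
accepted early when two successive flank sizes agree on the same absolute
junction, and a locus with no consistent coordinates is excluded
(`qc_reason = "discordant"`). Flanks clipped below 50 bp at contig ends fail
QC rather than producing undefined behavior.

`call_tsd()` then applies an exact three-way contract: the TSD is the
longest string that is simultaneously a suffix of the left flank, equal to
the sequence ending the inserted block (located by the net inserted length,
so a degraded downstream copy cannot shift the search), and present once at
the empty-site junction. By default all three comparisons are exact —
observed TSDs show near-perfect three-way identity, and the exact contract
is what makes simulator round-trips byte-exact — with a `tsd_max_mismatch`
option for sensitivity studies. If instead the flanks leave uncovered bases
on the empty side, those are a target site deletion, and a duplication is
then excluded by construction. QC drops refined inserts shorter than 50 bp
and loci with fewer than 30 inserted bases outside the TSD.

Two LINE-1-specific false-positive filters remove internal deletions of
pre-existing elements: the insert itself must be ≥70% LINE-1 by annotation
(HAL-family LINEs never count), and loci embedded in a larger annotated
LINE-1 must show a TSD of ≥10 bp.

## Hallmarks

Orientation is voted by annotation segments of ≥20 bp overlapping the
insert (unanimous → oriented; conflicting → "ambiguous", retained but
skipped for poly(A); none → removed). The poly(A) search walks the sequence
between TSDs for A-runs (plus) or T-runs (minus) whose gap to the element's
3' junction is ≤5 bp, keeps the longest (ties: nearest the junction — the
biological prior), and reports runs of ≥10 bp. The gap is measured to the
called TSD's inner edge whenever any TSD exists, else to the insert
boundary. Endonuclease sites are only read at loci with a high-confidence
TSD (≥10 bp) and a defined orientation: two bases upstream of the 5' TSD
plus the first five TSD bases, reverse-complemented for plus loci and
mirrored for minus loci so that both orientations superimpose as TTTTTAA in
the pooled logo (`logo_matrix()`).

Classification is two-tier. Stringent: TSD ≥10 bp and/or poly(A) ≥10 bp at
gap ≤5 ("both", "tsd_only", "polya_only", "neither", "ambiguous"). Relaxed:
TSD ≥7 bp counts, and degraded-tail evidence is any 15 bp window containing
≥10 orientation-appropriate bases within 30 bp of the TSD (windows scanned
at stride 1; the spec of the window carries no stride, and stride 1 is the
most permissive deterministic choice). Relaxation is monotone by
construction: every stringent "both" is a relaxed "both". Subfamily labels
come from annotation segments ≥20 bp over the between-TSD interval, with
SINEC_Cf and SINEC2A1_Cf collapsed into the single label "SINEC_Cf/2A1"
(their tRNA-derived heads are identical) and multi-subfamily loci reported
as unresolved.

## Cohort aggregation and phylogenetics

Loci from all comparisons are placed on outgroup coordinates, restricted to
autosomal regions callable in every comparison (intersection of per-pair
single-coverage regions minus outgroup exclusions; chrX is excluded from
multi-sample analyses by default because its evolutionary history and
assembly quality differ), and merged by single-linkage clustering at ≤100 bp.
A merged cluster is discarded as "more than one variant" when it mixes
element classes or receives two calls from one comparison — one event seen
in several samples is one variant. Presence states follow from the pairwise
design: a sample whose comparison called the variant is present (insertion
direction) or absent (deletion direction); a sample whose comparison shows
no variant shares the outgroup state. The resulting matrix gains an
all-absent "ancestor" pseudo-sample.

p-distances are simply the proportion of loci at which two samples differ
(two-state characters, no correction — and any two-state-to-nucleotide
encoding gives identical p-distances). Trees are classic Saitou–Nei
neighbor joining (via ape) with negative branch lengths clamped to zero and
the deficit shifted to the sister edge; support comes from resampling loci
with replacement (default 1,000 replicates) and counting bipartitions of the
full-data tree, which is then rooted on the ancestor. A locus "fits" the
rooted tree when its carrier set equals the leaf set under exactly one edge;
fitting loci are counted per branch and the rest tallied by pattern. The
ancestor participates in distances and rooting but not in branch
assignment.

## Rates

For each comparison, generations since divergence are

$$\hat g = \frac{\mathrm{SNV} \times 0.5}{L_{\mathrm{aligned}} \times \mu},$$

with SNVs and the aligned autosomal length both filtered against the
target-genome exclusion regions, and the per-birth denominator is
$N = \hat g / (\text{insertion count})$, per branch: each sample contributes
its query-side counts, and the outgroup branch is counted once via the
target-side counts of a designated comparison (avoiding counting the
outgroup once per pair). The cohort average is the arithmetic mean of the
per-branch denominators. Stringent estimates restrict to loci with TSD
≥10 bp, and every denominator is rescaled to the mutation-rate bounds as
$N \times \mu / \mu_{\mathrm{bound}}$ (generations scale as $1/\mu$ with
counts fixed). Reported denominators are rounded half-up to one decimal.
Published rates from other studies are rescaled linearly in $1/\mu$
(phylogeny-calibrated), linearly in $N_e$ (population-model), or not at all
(pedigree). Two aligned-length conventions exist in practice — a common
callable length shared by all comparisons versus each pair's own aligned
length — and they yield slightly different cohort averages; retrodiff uses
the per-pair length for rates (each comparison's SNVs are counted on its own
footprint) and the common callable set only for multi-sample locus
aggregation. The simulator's aligned-region emitter reports the homologous
footprint (pair-distinguishing insert blocks excluded); at genome scale the
difference is negligible, at simulator scale it removes a length bias from
the divergence estimator.

`heterozygous_fraction()` intersects dimorphic loci with heterozygous
deletion calls at ≥90% reciprocal overlap, and
`expected_pairwise_coalescence()` returns $2 N_e$ generations.

## 3' transductions

For dimorphic LINE-1 loci, the candidate transduction is the sequence from
the 3' end of the longest intersecting LINE-1 annotation to the end of the
refined insert, read in element orientation. Because the refined insert
already excludes TSD copies, TSDs never enter candidates (the source
procedure strips TSDs only when ≥10 bp; ours never includes them).
Candidates shorter than 25 bp, or with fewer than 25 unmasked bases after
DUST-style masking (64 bp windows, score threshold 20 on the 10-scaled
triplet statistic, with masking confined to dense tracts of repeated
triplets), are discarded; the original unmasked sequence is then searched
against the outgroup genome by a deterministic seed-and-extend aligner
(11-mer exact seeds on both strands, local extension scored +1/−2 with gap
open 4 and extend 1 via Biostrings). Hits require ≥95% identity, ≥25
matching bases, ≥25 aligned unmasked query bases, a target span within
100 bp of the query length, an autosome/chrX target, and a distance of more
than 10 kb from the locus itself; candidates with more than 50 raw
alignments and loci with more than 5 surviving hits are voided. A hit is
parent-adjacent when an outgroup LINE-1 annotation within 50 bp lies
upstream in its own orientation with concordant strand (annotations wholly
inside or containing the hit are ignored); hits merged at ≤100 bp form
source clusters, and clusters backing more than one independent insertion
are flagged recurrent.

## Problem sizes used by the test and acceptance suites

These are desk-scale choices made so that the whole validation runs on a
laptop-class machine; all rates, branch-length ratios and thresholds are the
study-scale values, and counts simply scale with genome length:

* Truth recovery / phylogeny: 7 samples on the study-shaped ultrametric
  tree (branch lengths scaled 0.65), 1 Mb genomes, ≈500 implanted
  insertions, 1,000 bootstrap replicates.
* Parameter recovery: two-sample cohorts, 10,000 generations per branch,
  1 Mb genomes, rates 1/20 (SINEC) and 1/150 (LINE-1), 10 seeds in the test
  suite (5 in the acceptance script).
* Unit fixtures: 0.4 Mb 7-sample bundle; 10 kb toys for the brute-force
  interval oracles.

## Known limitations

* The exact-match TSD contract undercounts hallmarks on mutationally
  degraded loci; the relaxed tier quantifies, but does not remove, that
  conservatism.
* Twin-priming rearrangements (inverted/truncated LINE-1s) are not
  modeled or resolved; such loci would pass through refinement but their
  poly(A) calls would be unreliable, mirroring their exclusion from the
  source analysis.
* The seed-and-extend search is a desk-scale stand-in tuned for unique,
  near-identical matches; it does not reproduce a genome aligner's behavior
  in large repeat families.
* Presence inference assumes every merged locus is callable in every
  comparison; the callable-region filter enforces this but discards real
  loci near exclusion regions.
* Simulated singleton fractions depend on the chosen tree's
  terminal/internal branch ratio and will not match a real cohort's deep
  ancestral polymorphism structure; tree-recovery tests are therefore about
  topology and support, not about reproducing published sharing fractions.
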