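---
title: "Methods and design notes for mitocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mitocompare implements the comparative statistics used to characterise
compact animal mitochondrial genomes — the actiniarian (sea anemone)
arrangement in particular: a circular molecule of roughly 16.6 kb with
13 energy-pathway protein-coding genes (PCGs), two tRNAs and two rRNAs,
typically all on the heavy strand. This vignette records the statistical
definitions, the tunable parameters and their defaults, the design
decisions taken where conventions genuinely differ between tools, and
what the synthetic-data generator does and does not emulate.

## Coordinates and annotation

Internally all features are 0-based, half-open `[start, end)`; all file
formats (GenBank, feature TSVs) are 1-based inclusive. A feature that
wraps the origin of a circular molecule is represented with
`end > genome length` so that `end − start` is always its length and
extraction is plain modular arithmetic. Gene names are normalized
through an editable synonym table (`inst/extdata/gene_synonyms.tsv`);
unknown names pass through verbatim so non-canonical ORFs are kept, not
silently dropped. Ambiguity codes other than N are rejected at parse
time: every downstream statistic is defined on the four bases, and a
loud early failure beats a silently biased denominator. N is accepted,
tracked, and excluded from denominators.

## Composition and skew

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C). Two
conventions had to be fixed where practice varies:

* N bases are excluded from skew and percentage denominators (the
  statistics are defined on unambiguous bases); the N count is reported
  separately.
* Per-gene skews are measured on the coding (extracted) strand. In the
  focal arrangement every gene is on the heavy strand so this equals the
  genome strand, but for mixed-strand genomes it keeps per-gene values
  comparable across species.
* The "PCGs" aggregate is the 13 canonical CDS concatenated in canonical
  circular order, stop codons included. Published totals are ambiguous
  about stop codons (a 12,105 bp PCG set is 4,035 codons with stops and
  4,022 without); the implementation reports both conventions — stop
  codons are tallied separately by `count_codons()` — rather than
  guessing which one produced a printed number.

Intergenic regions (IGN) are the complement of the union of feature
spans on the circle, split into maximal runs; overlap between features
is tolerated (trimmed, with a warning) because curated records
occasionally overlap by a codon. The CR-like motif scan matches
`G A{n,} T` with the A-run taken maximally, left to right,
non-overlapping. The minimum run length defaults to 3 and is
configurable: the motif is conventionally written G(A)nT without a
stated n, so the threshold is an explicit parameter, not a hidden
constant. On circular scans the sequence is extended by its own prefix
so matches may cross the origin.

## Codon usage

The genetic code defaults to NCBI translation table 4
(mold/protozoan/coelenterate mitochondrial: stops TAA/TAG, TGA = Trp),
taken from Biostrings, with the table id configurable. Stop codons are
excluded from usage counts and percentages and tallied separately.
Codons containing N are skipped and counted, never imputed. RSCU is
count over synonymous-family mean; an unexpressed family is flagged NA
rather than 0, because 0 would masquerade as extreme bias.

The residue classes used in the depth contrast are nonpolar
{G, A, V, L, I, P, F, M, W}, polar-uncharged {S, T, C, Y, N, Q} and
charged {D, E, K, R, H}. This is a documented choice of a standard
classification (histidine counted as charged), not a table copied from
any one source.

The depth-group comparison uses two-sided Welch t-tests per amino acid
and per class. Welch rather than pooled variance because realistic
group sizes are tiny and unbalanced (a "deep" group of two is the
motivating case) and equality of variances is not defensible there; any
group with n < 3 carries a warning flag on every row. No
multiple-testing correction is applied to the primary p values — the
comparison is reported the way such mitogenome surveys report it — but
a Bonferroni column is always emitted so a reader can make the
conservative call, and the simulated null analysis in
`analysis/03_codon_usage.R` shows why: with 23 tests and n = 2 vs 4,
nominal hits at p < 0.05 appear by chance and vanish after correction.

## Nucleotide diversity

Pi is the mean over all n(n−1)/2 sequence pairs of the per-site
difference proportion. The default deletion rule is *complete*: a site
with a gap or N in any sequence is removed from numerator and
denominator for every pair, matching the default behaviour of the
standard sliding-window tool for this statistic; a pairwise-deletion
mode is available behind a flag. No Jukes–Cantor or other correction is
applied to Pi — it is the raw diversity.

Sliding windows are `[k·step, k·step + window)` on alignment
coordinates, default 100 bp window and 25 bp step; trailing partial
windows are dropped (a 90 bp tail would otherwise report a
high-variance pseudo-window), and midpoints are reported for plotting.
With `step == window` and no masked sites, the site-weighted mean of
window Pi equals whole-alignment Pi to machine precision, which the
tests assert. Alignments shorter than one window fall back to per-gene
Pi with a warning. Ranking across genes breaks ties by canonical gene
order so that output is deterministic.

## Gene order

Orders are circular sequences of signed gene labels (light-strand genes
carry a minus sign). The breakpoint distance between two orders first
restricts both to their shared gene set (gained/lost ORFs and introns
should not inflate the distance), then counts signed, directed circular
adjacencies of one absent from the other. Rotation is free; reflection
(reading the whole molecule from the other strand) is deliberately NOT
normalized away, because strand is displayed explicitly in mitogenome
order maps and a whole-molecule flip is a real difference there. tRNAs
are included in the order — the canonical actiniarian order is quoted
with its two tRNAs. The distance is 0 iff the restricted orders are
identical as signed circular sequences, it is symmetric, and it agrees
with brute-force adjacency enumeration on all small orders (tested).

## NG86 dN/dS

Site counting: each codon position contributes the fraction of its
single-nucleotide changes that are synonymous, with changes creating a
stop excluded from the possible-change set; S + N = 3 × codons by
construction. Difference counting: for a codon pair differing at d
positions, all d! orderings of the changes are enumerated, orderings
passing through a stop are discarded, and synonymous/nonsynonymous step
counts are averaged over the survivors with equal weight. If no
stop-free ordering exists (rare but possible), the codon's differences
are classified by direct per-position comparison and the pair is
flagged. Both distances use the Jukes–Cantor correction
d = −(3/4)·ln(1 − (4/3)p); p ≥ 3/4 yields a flagged undefined distance,
never a clamped number, and ω is undefined when dS = 0 (flags
`identical`, `saturated`, `dS_zero` distinguish the reasons).

For speed, per-codon site counts and the 64×64 pathway-averaged
difference counts are precomputed once per genetic code and memoised;
the test suite verifies the tables against independent recursive
pathway enumeration, so the fast path and the oracle stay separate.

The depth contrast is a *pairwise-mean* statistic: foreground ω is the
mean pairwise ω among deep-group genomes (with only one deep genome it
falls back to deep-vs-shallow pairs and says so in
`foreground_kind`), background ω the mean among shallow-only pairs, and
the fold ratio is background/foreground. This is an auditable counting
stand-in for a likelihood branch-model contrast, and every output row
carries `method = "NG86-pairwise"` so the two are never conflated.
Likelihood branch and branch-site models, LRTs and site-level posterior
detection are out of scope.

## The synthetic-data generator

`generate_ancestor()` lays out genes and spacers to a plan. The default
plan is the canonical 17-gene actiniarian order with realistic lengths:
12,105 bp of PCGs (4,035 codons including stops), rRNAs of 1,055 and
2,162 bp, two ~70 bp tRNAs, and 17 spacers totalling 1,112 bp — the
longest, 223 bp, between ND5 and ND1, and a 147 bp spacer between
s-rRNA and cox2 carrying an explicit G(A)nT motif (default run of six
A's) at its midpoint. Composition targets default to A+T 62.4%, AT skew
−0.12, GC skew +0.12 (AT% overrides of 54.9/58.9 for the rRNAs).

Two numerical choices make the targets reliable rather than merely
expected:

* Codon weights are the product of base probabilities, but excluding
  stop codons (and applying any codon-bias override) shifts the pool's
  base content; the underlying probabilities are therefore calibrated by
  fixed-point iteration until the sense-codon distribution's expected
  composition hits the target.
* Bases and codons are drawn by largest-remainder quota apportionment
  and then shuffled with the seeded RNG. Realized composition thus
  matches the target to within one unit per category (realized GC skew
  0.120 ± 0.001 at 16.6 kb across seeds) while the arrangement — and
  everything downstream of substitution — remains random and
  byte-reproducible under a fixed seed.

`evolve_family()` descends a star tree: each tip accumulates candidate
substitutions at `branch_length × per-gene rate multiplier` expected
events per site. Within CDS a candidate change is classified under the
code; synonymous changes are always accepted, nonsynonymous changes with
probability the branch's ω, stop-creating changes never, and the stop
codons themselves are frozen. ω is thus imposed by acceptance-thinning
— simple, auditable, and exactly the quantity NG86 estimates — rather
than by codon-matrix exponentiation. Deeper topologies can be composed
by evolving a tip again as a new ancestor. Note one consequence used in
`analysis/01_simulate.R`: CDS multipliers are candidate-change rates
(realized rates are thinned by roughly fS + (1 − fS)·ω at ω ≈ 0.1),
while RNA genes evolve neutrally, so multipliers that should produce a
given *realized* ranking must put RNA genes on the realized scale.

What the generator does **not** emulate: indels (alignments stay
trivial, which is why the diversity stage needs no aligner),
recombination, heteroplasmy, secondary-structure-aware rRNA/tRNA
evolution, gene rearrangement, introns and optional ORFs, and
context-dependent mutation. Passing recovery tests on these simulations
therefore demonstrates correctness of the estimators under clean
conditions — not robustness to misalignment, saturation or annotation
error in real data.

## Problem sizes and test design

The property suites check formula identities against independent
brute-force oracles (motif scan by substring enumeration, Pi by direct
recount, NG86 by recursive pathway enumeration, breakpoints by 2-gram
scans) on randomized cases at fixed seeds. The recovery suites use the
sizes at which the estimators are meant to operate: composition targets
on full 16.6 kb genomes over 10 seeds; Pi rate-ranking (atp8 fastest,
l-rRNA slowest) on 4-tip families over 10 seeds; ω recovery on
3,000-codon pairs, 10 replicates at each true ω of 0.05, 0.2 and 1.0
(relative bias of the replicate mean below 20%); and the group contrast
on six genomes at true ω 0.05 vs 0.12 (fold ratio 2.4 recovered within
±30%). The same computations, re-run from scratch, form
`scripts/acceptance.R`.

## Known limitations

* The NG86 pairwise contrast averages over pairs, so shared branches
  enter multiple pairs and the "foreground"/"background" means are not
  independent observations; the fold ratio is descriptive, not a test
  statistic.
* Equal weighting of substitution pathways (classic NG86) ignores
  transition/transversion bias; with strong bias, dS is typically
  underestimated and ω overestimated.
* Complete deletion discards entire columns; for very gappy alignments
  the pairwise-deletion flag retains more signal at the cost of
  pair-specific denominators.
* The GenBank reader is a minimal flat-file parser for single-record
  mitogenome depositions (LOCUS/FEATURES/ORIGIN, `a..b`,
  `complement()`, two-segment origin-spanning `join()`); it is not a
  general GenBank parser.
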