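---
title: "Methods: assembly comparison, variant classification and validation in svmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly comparison, variant classification and validation in svmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

svmap discovers structural variants (SVs) by comparing two genome
assemblies directly, rather than by interpreting short-read mapping
signals.  This vignette describes the model behind each stage, the
tunable parameters and their defaults, the synthetic data used to test
the package, and the design choices made where more than one reasonable
contract existed.

## Anchoring and chaining

The comparison starts from **maximal exact matches** (MEMs): substrings
shared identically by the two assemblies that cannot be extended on
either side.  By default only matches of at least `min_match = 20` bp
whose reference substring occurs exactly once in the whole reference are
kept, which suppresses anchor noise inside dispersed repeats.  `N`
never matches anything — not even another `N` — so masked intervals
(BED/GFF3) can be excluded from anchoring while base-level alignment
later still sees the real sequence.

Matches on one (reference sequence, query sequence, strand) group are
chained into collinear **clusters** by dynamic programming maximising
total matched length.  Two consecutive matches may be chained when

* their separation `max(ref_gap, qry_gap)` is at most `s = 200` bp,
* their diagonal drift `|ref_gap − qry_gap|` is at most `f = 0.12`
  times the separation, and
* they overlap a neighbour by at most 20 bp.

Chains with less than `l = 100` bp of total match are discarded; the
100-bp floor is what makes duplicates of 100 bp and longer detectable.
Ties in the chaining score are broken toward the leftmost reference,
then query, coordinate.  The drift rule has a useful side effect: an
indel of any size between two anchors violates it, so indels always
break chains and reappear either as stitched gap columns (below) or as
block-boundary gaps.  The overlap cap keeps the two copies of a tandem
duplication in separate clusters, which is precisely the signal the CNV
caller consumes.

## Base-level alignment and one-to-one filtering

Each cluster is **filled** to a base-level alignment: anchors become
exact-match columns and inter-anchor gaps are resolved by affine-gap
global alignment (match +1, mismatch −1, gap open 2, gap extend 0.5 per
base).  Any affine scheme would do; this one is fixed so that the
package's alignments are reproducible and testable against an
unconstrained dynamic-programming oracle with the same scoring.

Filled blocks are then **filtered to one-to-one synteny**: a
maximum-weight subset of blocks mutually non-overlapping (beyond a
50-bp tolerance) along both genome axes, weight being anchored match
length.  Conflict components are solved exactly (by enumeration) up to
16 blocks and greedily above that; real conflict components are almost
always pairs.  Two refinements matter in practice:

* *Redundancy absorption.* A block contained in a heavier block on the
  same alignment diagonal is a fragment of the same homology, not a
  competing placement, and is removed before selection.
* *Rescue trimming.* A rejected block whose conflict is confined to its
  head or tail is trimmed back to the non-conflicting remainder and
  kept if at least 100 aligned bp survive.  Without this, the flank
  shared between the two copies of a tandem duplication would be
  discarded together with the redundant copy, and every SNP in that
  flank would be lost.

Finally, adjacent collinear blocks whose gaps on both genomes are below
100 bp are **stitched**, with the gap region aligned at base level.
Stitching restores continuity across small indels (which always break
chains) so they are emitted as small variants rather than silently
falling between blocks.

## Variant classification

* **Copy-number gains/losses.**  When the reference intervals of two
  clusters overlap by ≥ 100 bp while their query projections are
  disjoint, the overlap is duplicated in the query.  The query-side
  copy intervals are obtained by projecting the overlap through each
  cluster's anchors; a gap between the copies is reported as the
  *spacer* (the tandem-duplication-with-spacer geometry, as in the
  *Cyp28d1* region where an *Accord* LTR fragment separates the
  copies).  Running the comparison in both directions yields gains and
  losses.  Candidates whose unit is ≥ 80% repeat-annotated are dropped:
  what overlapping clusters detect there is TE-family homology, not a
  unique-sequence CNV.
* **Copy-number verification.**  Every surviving candidate is
  re-aligned to both genomes with maximal-match anchoring (uniqueness
  not required) and disjoint alignment chains covering ≥ 1 − `rco` of
  the candidate are counted as copies, allowing internal unaligned runs
  up to `qco` per copy (`c = 500`, `qco` = 10 kb, `rco` = 0.2).
  Candidates with equal counts in both genomes are rejected — the
  signature of diverged repeats present in both assemblies.
* **Insertions/deletions.**  A gap > 100 bp between adjacent synteny
  blocks in one genome, with a counterpart gap < 10% of its length in
  the other, is an insertion in the gapped genome.  Gap pairs large on
  both sides are flagged divergent and not called.  An indel whose
  footprint lies inside a verified CNV span is suppressed: it is the
  duplication seen a second time by the block geometry.
* **Inversions.**  A reverse-strand block of ≥ 100 bp flanked by
  forward-strand synteny on both sides.  Inversions ≥ 95% covered by
  repeat annotation are removed: a TE present in opposite orientations
  at homologous positions is not an inversion of unique sequence.
* **SNPs and small indels.**  A per-column walk over the one-to-one
  blocks emits substitutions and indels < 100 bp, left-aligned against
  the reference in the VCF convention.  Gap runs ≥ 100 bp inside a
  block are promoted to structural calls.
* **Complex events.**  CNV calls within 2 kb of each other are merged
  into one counted event; the total affected bp is tallied before
  merging.

TE status is assigned by annotation coverage of the variant sequence
(threshold 0.8, inclusive), using the annotation of the genome that
carries the sequence: query-side for insertions and gains, reference-
side for deletions, losses and inversions.  The generator therefore
emits repeat annotations for both genomes; with real data the
query-side annotation would come from a repeat masker run on that
assembly.

Variant polarity is reported explicitly relative to the query
(`INS_QRY`, `CNV_GAIN_QRY`, …) rather than as ancestral/derived states;
outgroup-based polarization is outside the package's scope.

## Comparative scaffolding

Contigs are aligned to reference chromosome arms, filtered to mutually
best alignments along the contig axis, and assigned to the arm holding
the largest share of their aligned bases, provided that share is at
least 40%; the share is computed over the contig's aligned bases, not
its length.  Orientation is the strand carrying the majority of aligned
bases (a choice the 40% rule does not determine; it is configurable).
Contigs are ordered by the start of their first alignment that does not
overlap the preceding contig's alignment, ties broken by longer aligned
length (an unresolved tie is an error at desk scale), joined with
exactly 100 Ns, and unplaced contigs keep their sequence under a `U`
prefix.  Output includes FASTA, an AGP v2.1 component map, and the
assignment table.

## Long-read validation

For each SV, reads spanning the variant with ≥ 250 aligned bp of flank
on both sides are *fully spanning*; reads covering one breakpoint with
sufficient flank on that side are *overlap-spanning*.  Per read,
`P_aligned` is aligned bases over read length and `R_gaps` is gap
columns (insertions plus deletions of the primary alignment) over read
length; supplementary alignments are not combined.  Verdicts:

* `STRINGENT` — ≥ 2 fully spanning reads with `P_aligned ≥ 0.995` and
  `R_gaps < 0.005`;
* `STANDARD` — ≥ 2 overlap-spanning reads *on each side* at the
  stringent quality thresholds (fully spanning reads count toward both
  sides, and distinct reads are required per side), or ≥ 2 fully
  spanning reads with `P_aligned ≥ 0.975` and `R_gaps < 0.025`;
* `UNVALIDATED` otherwise.

For simulated data the package maps reads itself with the same
anchor-and-fill machinery, using a wide chaining separation (20 kb) so
that a read crossing a structural difference still yields a single
alignment whose gap columns expose the difference.  Inter-anchor
regions too large to align at base level (beyond 10^6 cells) are
represented as paired insertion/deletion runs — the conservative choice
for `R_gaps`.  With real alignments, SAM/BAM input is consumed via
Rsamtools and the same metrics are taken from the CIGAR.

The discrimination test validates each true variant on the assembly
that carries it, and the same breakpoints on the assembly that lacks
the variants serve as decoys: reads genuinely disagree with that
assembly at those loci, which is exactly the assembly-error scenario
the criteria are meant to catch.  Note a structural limit of the
criteria themselves: a wrong assembly allele shorter than roughly
`0.025 ×` the read length contributes too few gap columns to push
`R_gaps` over the standard threshold, so decoy rejection depends on
variant size relative to read length.

## The synthetic study condition

The default generator configuration — the condition under which the
package's end-to-end claims are tested — is a 500-kb background
chromosome at GC 0.42 carrying 40 ancestral TE copies (six families,
one LTR-bearing, copies diverged 8% from consensus), from which a
derived chromosome is produced with 20 TE insertions (young copies, 2%
diverged), 10 other insertions (200–800 bp, echoing the observed
median of ~200 bp for non-TE events), 20 deletions (200–800 bp), 10
tandem duplications (300–3000 bp units, 5 with a 200–1500 bp LTR
fragment spacer), 5 inversions (500–3000 bp), SNPs at 0.5% and small
indels (1–30 bp) at 0.05%.  Long reads default to 20× coverage with a
log-normal length distribution (median ~8 kb) and 1% error split
60/25/15 among insertions, deletions and substitutions — the
corrected-long-read regime.  Paired-end reads default to 2×100 bp at
30×, insert 400 ± 40 bp.

Placement rules keep every implanted variant recoverable in principle:
SV footprints sit in unique sequence with 300-bp mutual clearance;
small indels keep 200 bp of clearance so the exact-sequence island
between events stays above the 100-bp cluster threshold; SNPs keep
50 bp.  The realized SNP count can fall slightly below the nominal
rate because of these clearance constraints.  Every stochastic choice
flows from one seed, and replaying the truth records against the
ancestral genome must reproduce the derived genome byte for byte — an
invariant the test suite asserts.

What the simulator does **not** emulate: diploid heterozygosity,
assembly errors, sequencing-signal-level artifacts, nested or
overlapping variants, segmental duplications of repeat-rich sequence,
and chimeric reads beyond a small uniform rate in the paired-end
projection.  Passing the end-to-end tests therefore demonstrates that
the algorithms implement their contracts on clean, fully-known input;
it does not by itself establish recall on real assemblies, where
repeat structure and assembly quality dominate.

## Downstream statistics

* **Fisher's method**: `X = −2 Σ ln p` against chi-square with `2k`
  degrees of freedom, for combining replicate Wilcoxon rank-sum tests.
* **Rank-sum test**: exact enumeration of the rank-sum distribution
  (average ranks under ties) for combined sizes ≤ 12, two-sided p as
  twice the smaller tail capped at 1; normal approximation with tie and
  continuity correction above that.
* **Temperature interpolation**: least-squares line through probe
  (position, temperature) readings; fly positions are predicted from
  the fitted line.
* **Paralog-specific FPKM**: `count / ((effective_len/10³) ×
  (total_mapped/10⁶))`, with effective length equal to transcript
  length minus the regions no copy-distinguishing read can cover.
* **Duplicate-allele frequency**: divergent pairs are the complement of
  properly oriented pairs; a sample is a carrier when divergent-pair
  count within ±500 bp of a candidate breakpoint reaches 3 and exceeds
  5× the sample's background divergent level (the peak statistic is not
  uniquely determined by "a clear peak and high signal-to-noise ratio",
  so these thresholds are explicit, configurable parameters).  Samples
  below the aligned-coverage floor or identical by descent to an
  earlier sample are excluded (IBD comes from a precomputed table; the
  second member of each pair is dropped), and populations with fewer
  than 10 retained samples are not reported.  Frequency is carriers
  over retained samples.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally; emitted TSV/VCF reports
are 1-based.  Empty inputs yield empty, correctly-typed tables rather
than errors; crossing anchors in a cluster are an error; a copy-number
candidate absent from both genomes reports (0, 0) with a warning; a
missing repeat annotation downgrades all affected calls to non-TE with
a warning.  Chance micro-overlaps between adjacent blocks (an anchor
extended past a junction by coincidental sequence identity) are trimmed
back, bounded at 20 bp.

## Problem sizes

The test-suite and reproduction-script runs use the default 500-kb
genome pair for the end-to-end checks, a 300-kb chromosome in 8 contigs
for the scaffolder round trip, 100 random ≤ 200-bp pairs for the
exact-match oracle, ≤ 500-bp intervals for the alignment oracle,
exhaustive rank-sum enumeration to combined size 10 with sampled
configurations at sizes 11–12, and 20 simulated samples for the
frequency estimator.  These sizes were chosen so a full run completes
in minutes on one CPU while every algorithmic branch is exercised.

## Alignment identity floor

Blocks entering one-to-one filtering in the full pipeline must reach
95% identity (`min_identity`).  Diverged repeat-family homology — two
TE copies of the same family aligned across non-homologous loci — sits
well below this floor, while genuine homologous blocks between two
strains sit far above it; without the floor such repeat-homology blocks
can occupy coordinate space inside a genuine flank and prevent its
rescue.  Copy-number calling consumes clusters, not filtered blocks,
so detection of diverged duplications is unaffected.

A companion rule makes rescue robust when a low-weight repeat-homology
block slips past the identity floor: a kept block lighter than a
quarter of the rescue candidate whose conflict lies strictly inside the
candidate's span is evicted in its favour.  Head/tail conflicts are
still resolved by trimming; only interior fragments — which cannot be
trimmed around — are evicted, and never a block of comparable weight.
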