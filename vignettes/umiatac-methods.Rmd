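---
title: "UMI-aware ATAC-seq: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI-aware ATAC-seq: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(umiatac)
```

## The problem

ATAC-seq measures chromatin accessibility by counting Tn5 transposase
insertion events. Libraries are PCR-amplified, so the standard remedy for
amplification bias is to collapse read pairs with identical mapping
coordinates to a single fragment. That remedy is too blunt: at high
sequencing depth, two *independent* Tn5 insertion events can produce
fragments with identical coordinates ("natural duplicates"), and the
probability of this grows with local accessibility. Coordinate
deduplication therefore removes real signal preferentially from the most
accessible — and most interesting — regions, flattening quantification and
weakening transcription-factor footprints.

When each molecule carries a unique molecular identifier (UMI) ahead of the
Tn5 mosaic-end (ME) sequence, the two cases separate cleanly:

* identical coordinates + identical UMI → PCR duplicate (remove);
* identical coordinates + different UMI → natural duplicate (keep, "rescued").

The package implements the full computational path for such libraries and a
simulator that generates every input with known ground truth. Throughout,
three counting modes are compared: **ND** (no deduplication), **CD**
(coordinate deduplication) and **UD** (UMI-aware deduplication).

## Read structure and preprocessing

Read 1 of a tagged library is `UMI + spacer + ME + genomic`. The UMI is the
first 6 bp; spacers of 6/13/20/25 bp exist only to create base diversity in
the first sequencing cycles and carry no identity, so everything between the
UMI and the 19-bp ME anchor (`AGATGTGTATAAGAGACAG`) is discarded.
`process_fastq()`:

1. strips the UMI (reads not longer than the UMI are rejected);
2. finds the smallest ME offset within 50 bp (exact match by default;
   `me_max_mismatches` relaxes this — exact is the conservative default
   because sequencing errors in the anchor are rare and a false anchor
   shifts the genomic start);
3. trims to the first genomic base and rejects trimmed reads shorter than
   30 bp;
4. appends the UMI to the read name (`name_UMI`) so it survives alignment.

Every input pair lands in exactly one of *kept*, *no-ME* or *too-short* —
the conservation invariant the tests check exactly. By default the UMI
comes from read 1 only: only the read-1 adapter carries a designed UMI, and
taking 6 bp off read 2 would discard genomic bases. `umi_from = "both"`
concatenates both mates' prefixes for libraries designed that way.

## Duplicate classification

Alignments are filtered to properly paired, primary records with both
mates' MAPQ above 30 and contigs outside a configurable exclusion list
(organellar genomes in plants, `chrM` in animals). Each template is reduced
to a fragment interval `(contig, start, end)` in 0-based half-open
coordinates, reconstructed from the leftmost mate's position and template
length. The duplicate key is the fragment interval, not per-mate 5'
positions; the two coincide for proper pairs under these filters, and the
fragment view matches the insertion-event interpretation (both fragment
ends are Tn5 insertions; orientation is deliberately not part of the key).

Within a coordinate group, UMI classes are formed by exact string equality
(default). One representative per class — highest summed base quality, ties
broken by name — is kept under UD; the best representative per group is the
CD survivor; every additional representative is *rescued*. An optional
Hamming-distance collapse (`umi_hamming = 1`) absorbs sequencing errors in
the UMI; UMIs containing `N` never merge with a different UMI under
collapsing. It is off by default because the simulator does not inject UMI
errors and real 6-bp UMIs at moderate depth rarely collide by single
errors; turning it on trades a small loss of true rescues for robustness to
UMI miscalls.

`kept_cd <= kept_ud <= kept_nd` holds for every input. With random 6-bp
UMIs the UD count undercounts true unique fragments only through UMI
collisions; the expected undercount is bounded by
`sum_coordinates C(m, 2) / 4^6` for `m` fragments sharing a coordinate, and
the acceptance suite verifies the realised undercount against this bound.

## Quantification

Each fragment contributes two insertion events: in 0-based half-open
coordinates the plus-strand event at `start + 4` and the minus-strand event
at `end - 6`, the standard "+4/−5" adjustment expressed 0-based. Fragments
shorter than 10 bp (where the shifted events would cross) are skipped and
counted. Events are binned into 250-bp half-open bins; the presumed PCR
duplication rate of a bin is `(ND − kept)/ND` with `kept` from CD or UD,
defined as 0 when ND is 0 (such bins are excluded from decile summaries,
where the rate is the object of interest). Decile analysis ranks bins by ND
accessibility, selects a top fraction (or a minimum-count threshold),
splits the selection into ten contiguous rank groups and reports per-decile
mean rates; decile ties are broken by genomic order. Track comparisons use
Pearson correlation of `log2(count + 1)`; the pseudocount of 1 is the usual
convention for count tracks with zeros.

Two counting units are supported: insertion events (two per fragment, the
default) and reads (one per fragment, assigned to the bin of its
plus-strand insertion site). The read unit exists because bin-level QC is
often reported per read pair; the insertion unit is the right one for
footprinting and is used everywhere else.

TSS enrichment has no single published formula; the package uses the
ENCODE-style convention — aggregate profile over ±1 kb, normalised by the
mean of the two outermost 100-bp edges, smoothed with a 51-bp moving
average, scored at the TSS — and documents it as convention-dependent.
FRiP is the fraction of insertion events inside merged peaks.

## Footprint scoring

For a candidate footprint of length `l_fp` (11–26 bp) with 35-bp shoulders,
the statistic is the product of two lower-tail binomial CDFs, one per
strand, with success probability `q = l_fp / (l_fp + l_sh)`:
`P = F(FP+; FP+ + SH+, q) · F(FP−; FP− + SH−, q)`, where `SH+` counts
plus-strand insertions in the upstream shoulder and `SH−` minus-strand
insertions in the downstream shoulder. The lower tail makes *depletion*
inside the footprint significant, which is the Wellington design. P-values
are handled in log space throughout (`log10 = TRUE`), so calling still
works far below double-precision underflow (a called footprint at deep
coverage can easily have `log10 P < -300`).

The footprint score is `log10(−log10 P)`. The inner logarithm is base 10 by
definition; the outer logarithm's base is not fixed by convention, and the
package uses base 10. The transform is strictly monotone either way, so
the calling threshold `P < 1e-30` is exactly equivalent to
`score > log10(30) ≈ 1.477` under this choice.

Scanning evaluates every candidate start and every footprint length
(step 1 over 11–26; the step is configurable), keeps the minimal P per
start, and accepts candidates below threshold in ascending P order with
greedy suppression of overlapping calls. The greedy rule emulates the
observed behaviour of footprint callers in which a strong call blocks the
identification of weaker overlapping candidates. Shoulder windows are
strictly outside the footprint interval. Candidates whose shoulders would
cross a contig boundary are skipped.

Footprint depth is
`FPD = (FKI/(2f) − FPI/L) / (FKI/(2f) + FPI/L)` with `f = 50` bp of flank
on each side (so the conventional `FKI/100`), bounded in [−1, 1], invariant
under uniform count scaling, and defined as 0 for the 0/0 case (no evidence
either way).

When footprint sets called under two modes are compared, footprints
overlapping by at least one base are *common*; the merged intervals are
then rescored under both insertion tracks at the same fixed interval (with
`l_fp` clipped to [11, 26] for `q`), so score differences reflect the
tracks and not interval choice. Peak sets are prepared for scanning by
union-merging and extending intervals shorter than 100 bp symmetrically
about their midpoint to exactly 100 bp (the extension direction is not
dictated by any convention; symmetric is the neutral choice).

## Motif-overlap significance

A footprint counts as overlapping the motif set when at least 50% of the
*footprint's* length is covered (the reference side of the 50% rule is the
natural reading for "footprints overlapping motifs"; a reciprocal mode is
available). The null distribution re-places footprints uniformly within the
peak space: a peak is chosen with probability proportional to its number of
feasible start positions and the start is uniform, so placement is uniform
over all feasible positions across the whole peak set; shuffled intervals
may overlap each other, and each placement stays within a single peak. With
100 shuffles the observed fraction is tested one-sided (upper tail) by a
Z-test — enrichment is the hypothesis of interest, and the tiny P-values
such tests produce are only reachable one-sided under the normal
approximation. Identical seeds give bit-identical results.

## The simulator

`sim_model()` describes a per-bp insertion-rate landscape: background rate,
peak intervals with multipliers, footprint intervals (inside peaks) with a
depletion factor, and a fragment-length mixture. Defaults emulate ATAC-seq
insert sizes with a sub-nucleosomal component (mean 60 bp, sd 15) and a
mono-nucleosomal component (mean 200 bp, sd 25), equally weighted and
truncated below 40 bp by rejection (no probability atom at the floor).

`draw_fragments()` draws **both** fragment ends from the rate field: the
plus-strand insertion position is sampled from the field, the length from
the mixture, and the implied minus-strand position is accepted by thinning
proportional to the field. The joint end density at a position therefore
scales with the product of the rates at the two ends — deep inside a peak
with multiplier *m* it goes like *m²* relative to deep background. This is
the property footprinting needs (depletion is visible on both strands) and
is what the tests assert. A consequence worth knowing: a "10× peak" spans
a ~100× end-density range against background.

`amplify()` draws per-fragment copy numbers as
`1 + NegBinom(mu = mean_copies − 1, size = dispersion)` — minimum one copy,
mean exactly `mean_copies`, overdispersed to emulate unequal amplification
efficiencies (any overdispersed law would do; the negative binomial is the
standard choice and the parameters are exposed). `depth` reads are sampled
without replacement from the copy pool; the first sampled copy of each
fragment is the original. Natural duplicates arise organically from the
finite coordinate space at high depth — no collisions are injected.

`emit_fastq()` writes the tagged library (UMI + random spacer padding + ME
+ genomic prefix; read 2 is the reverse-complemented suffix; constant "I"
qualities) plus a per-read truth ledger; `emit_alignments()` bypasses the
external aligner and emits properly paired records at the exact simulated
coordinates with MAPQ 60 (real data would go through `bwa mem`, which is
out of scope here). Everything is deterministic under a seed.

What the simulator does **not** model: sequencing errors (so UMI Hamming
collapsing is exercised only by dedicated unit fixtures), GC- or
length-dependent amplification bias, optical duplicates, mappability, or
quality decay. Passing tests therefore demonstrate the statistical
machinery under the stated generative model, not robustness to every
artefact of real libraries.

## Problem sizes used by the test suite

The acceptance experiments are sized so that Monte Carlo error is small
relative to the effects being tested while the whole suite stays fast on a
single CPU:

* ground-truth recovery: 100-kb genome, ten 1-kb peaks at 10× background,
  50,000 true fragments, mean PCR copies 3, 120,000 read pairs;
* duplication-rate bias and track correlations: 1-Mb genome, 200 1-kb
  peaks with multipliers log-spaced 1–30, 2,000,000 true fragments, the
  whole ~6M-read copy pool sequenced (saturating). At this scale the
  per-decile PCR-rate sampling noise (~0.1–0.2 percentage points) is well
  below the natural-duplicate gradient across deciles;
* footprint sensitivity: 100-kb genome, ten 1-kb peaks at 25× over a 0.2
  background, twenty embedded 15-bp footprints at depletion 0.9, 600,000
  fragments — dense enough that shoulder counts saturate the calling
  threshold under both CD and UD;
* shuffle-test calibration: 200 replicate tests of 200 shuffled 15-bp
  intervals against 250 motif sites in fifty 1-kb peaks, 100 shuffles each.

## Numerical and degenerate-input choices

* Binomial CDFs with zero trials are 1; `wellington_pvalue(..., log10 =
  TRUE)` never leaves log space.
* `footprint_score(0)` is `+Inf` with a warning; `P >= 1` gives `-Inf`.
* `duplication_rate(0, 0)` is 0; FPD of 0/0 is 0.
* Empty event sets: FRiP and TSS enrichment return `NA` with a warning
  rather than fabricating a value.
* Degenerate shuffle nulls (zero variance) return `NA` z and P with a
  warning.
* Fragments shorter than 10 bp are skipped (and counted) when converting
  to insertion events.
* Representative selection breaks quality ties by lexicographic name, so
  classification is invariant to input record order.

## Limitations

The dedup key is the fragment interval; libraries with many improper pairs
or split alignments would need a per-mate key. The TSS enrichment score is
convention-dependent and should not be compared across tools without
checking the convention. The shuffle test conditions on the peak set and
interval lengths but not on local GC or mappability. Wellington-style
scanning reports maximal non-overlapping candidates; footprints closer
than the suppression radius to a stronger call are intentionally not
reported.
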