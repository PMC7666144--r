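# umiatac

UMI-aware deduplication, quantification and footprinting for ATAC-seq.

## The problem

ATAC-seq counts Tn5 transposase insertion events to measure chromatin
accessibility and to find transcription-factor footprints. Because libraries
are PCR-amplified, read pairs with identical mapping coordinates are
conventionally collapsed to one fragment. At high depth, however, two
*independent* Tn5 insertion events can yield identical fragments ("natural
duplicates"), and the chance of that grows with local accessibility —
coordinate deduplication therefore deletes real signal preferentially from
the most accessible regions and flattens footprints.

When each molecule carries a unique molecular identifier (UMI) ahead of the
19-bp Tn5 mosaic-end sequence (`AGATGTGTATAAGAGACAG`), the two cases
separate: *same coordinates + same UMI* is a PCR duplicate; *same
coordinates + different UMI* is an independent insertion event that should
be **rescued**. `umiatac` implements the full computational path for such
libraries and compares three counting modes throughout: **ND** (no
deduplication), **CD** (coordinate deduplication) and **UD** (UMI-aware
deduplication).

The core statistics, in the field's standard notation:

* presumed PCR duplication rate per 250-bp bin: `(ND − kept)/ND`, with
  `kept` from CD or UD;
* Tn5 insertion sites from a fragment `[start, end)` (0-based half-open):
  plus-strand event at `start + 4`, minus-strand event at `end − 6`
  (the "+4/−5" shift);
* Wellington footprint P-value for a candidate of length `l_FP` (11–26 bp)
  with 35-bp shoulders, `q = l_FP/(l_FP + l_SH)`:
  `P = F(FP⁺; FP⁺+SH⁺, q) · F(FP⁻; FP⁻+SH⁻, q)` with `F` the lower-tail
  binomial CDF; footprint score `log₁₀(−log₁₀ P)`; calling threshold
  `P < 10⁻³⁰`;
* footprint depth `FPD = (FKI/100 − FPI/L)/(FKI/100 + FPI/L)` with `FKI`
  the insertions in the 50-bp flanks, `FPI` the insertions inside, `L` the
  footprint length;
* motif-overlap significance: footprints re-placed uniformly within peaks
  100 times, one-sided Z-test on the observed ≥50% overlap fraction.

A fully seeded simulator (genome, accessibility landscape with embedded
footprints, fragment library with UMIs, PCR amplification, FASTQ/alignment
emission) provides every input with a complete ground-truth ledger, so the
whole pipeline is testable without external data.

## Worked example

Simulate a saturated library on a 100-kb genome (ten 1-kb peaks at 10×
background, twenty embedded footprints), deduplicate, quantify and call
footprints:

```r
library(umiatac)

contigs <- c(chr1 = 100000L)
model <- sim_peak_model(contigs, n_peaks = 10, peak_width = 1000,
                        multipliers = 10, footprints_per_peak = 2,
                        footprint_length = 15, depletion = 0.9)
frags <- draw_fragments(model, 50000, seed = 1)
reads <- amplify(frags, mean_copies = 3, depth = 120000, seed = 2)
aln <- emit_alignments(reads, contigs)

classified <- classify_fragments(aln$fragments)
print(dedup_stats(classified))
#> Fragment deduplication:
#>   fragments (ND):  120000
#>   kept CD:         45980
#>   kept UD:         46848
#>   PCR duplicates:  73152
#>   rescued:         868 (1.2% of presumed duplicates, 0.7% of total)

bins <- binned_modes(classified, contigs)
compare_tracks(bins$ud, bins$nd)$r_squared
#> R^2 of log2 UD vs ND insertion counts: 0.987

events <- insertions_from_fragments(dedup_fragments(classified, "ud"))
fp <- scan_footprints(events, prepare_regions(model$peaks), contigs)
nrow(fp)
#> footprints called at P < 1e-30: 18

print(shuffle_test(fp[, c("contig", "start", "end")], model$footprints,
                   model$peaks, n_shuffles = 100, seed = 3))
#> Shuffle-within-peaks overlap test:
#>   observed fraction: 1.0000
#>   null mean (sd):    0.0356 (0.0457), n = 100 shuffles
#>   z = 21.10, one-sided P = 4.33e-99
```

Reading the numbers: of 120,000 sequenced fragments, UD keeps 46,848 —
868 more than CD. Those 868 are independent insertion events that
coordinate deduplication would have discarded as PCR copies (the simulation
truth ledger confirms the classification exactly; see the test suite). The
UD track correlates with the undeduplicated track at R² = 0.987, 18 of the
20 embedded footprints are recovered at `P < 10⁻³⁰`, and their overlap with
the true embedded sites is far beyond chance (z = 21).

Real libraries enter the same path through `process_fastq()` (UMI
extraction + ME trimming of raw FASTQ), an external aligner such as
`bwa mem`, and `dedup_alignments()` on the coordinate-sorted BAM. A thin
command-line wrapper with `preprocess`, `dedup`, `quantify`, `footprint`,
`shuffle-test` and `simulate` subcommands is installed at
`inst/cli/umiatac.R`.

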