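---
title: "Methods: maximum-scoring-island CNV detection and validation"
author: "swcnv maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-scoring-island CNV detection and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcnv)
```

# Scope

`swcnv` detects copy-number variable regions in array-CGH log2-ratio
profiles with a one-dimensional Smith–Waterman ("maximum scoring island")
dynamic program, screens the resulting segments for spurious signal,
classifies them as known or novel against DGV-style catalogues, and
cross-checks candidate regions against sequencing alignments through a
per-base pileup (depth, nucleotide counts, allele fractions, SNP calls and
a read-depth deletion scan). Deterministic simulators generate every kind
of input the package consumes, so each analysis step can be validated
against planted truth.

This vignette records the statistical model, the parameter conventions,
and the numerical choices that affect results.

# Segmentation model

## Scores

For a vector of log2 ratios $x_1,\dots,x_n$ on one chromosome of one
sample, dispersion is estimated by the *unscaled* median absolute
deviation,

$$\mathrm{MAD}(x) = \mathrm{median}_i\,|x_i - \mathrm{median}(x)|,$$

deliberately without the Gaussian consistency factor 1.4826: the
threshold multiplier $k$ is a user-facing tuning knob, and keeping the
estimator raw makes $k$'s meaning independent of a normality assumption.
Probe scores are

$$s_i^{\text{gain}} = x_i - (\mathrm{median}(x) + k\,\mathrm{MAD}), \qquad
  s_i^{\text{loss}} = (\mathrm{median}(x) - k\,\mathrm{MAD}) - x_i.$$

If $\mathrm{MAD}(x)=0$ (a constant or near-constant profile) the
threshold carries no information; `detectCnv()` refuses to segment and
asks for an explicit `absThreshold` rather than silently calling every
probe or none. When more than half the probes sit inside true events the
median itself shifts; the `scope = "genome"` option of `detectAll()`
freezes one genome-wide threshold for exactly this situation.

## Islands

The Smith–Waterman recursion
$S_i = \max(0,\, S_{i-1} + s_i)$, $S_0 = 0$, is evaluated in closed form:
with prefix sums $P_i = \sum_{j\le i} s_j$,

$$S_i = P_i - \min\!\big(0, \min_{j \le i} P_j\big),$$

which vectorizes to `P - pmin(cummin(P), 0)`. An *island* is a maximal
run of $S_i > 0$; it is reported from the run start to the **first**
index attaining the run's maximum of $S$ (ties break leftmost, so
results do not depend on floating-point traversal order), with the run
maximum as its score. A value of exactly 0 terminates a run. Islands
with fewer than $L$ probes (the *island block length*, `minIslandProbes`)
are discarded. Missing probes are excised before the recursion and
island coordinates are mapped back through the surviving probes, so an
island's `n_probes` counts informative probes only, while `first_probe`
and `last_probe` index the full chromosome probe order.

## What strictness buys, precisely

Raising $L$ can only remove whole islands, so both the segment count
and the spatial extent of the call set are monotone in $L$ — an exact
theorem the tests assert. For $k$ the situation is subtler, because
raising $k$ subtracts a constant from every score, which can
*rearrange* islands, not just shrink them:

* spatial containment fails — scores $(2, -1, 1)$ versus a threshold
  shift of $0.5$ turn one island into two, one of which lies outside
  the original;
* even the segment **count** can increase when $L$ is very small: a
  stricter threshold can fragment one long island into several pieces
  that each still pass a lenient length filter (observed at $L = 3$
  when moving $k$ from 3 to 4 on ~6% of random profiles).

At practical island lengths ($L \ge 5$, the default) the fragments fall
below the length filter and the count is non-increasing in $k$ on
every dataset we generate; that is the form of the strictness property
asserted by the test suite and the acceptance script. The false general
invariants are documented here rather than asserted.

## Parameters and defaults

* `madMultiplier` ($k$, default 3) — three robust standard-deviation
  equivalents; the conventional balance between sensitivity and the
  false-discovery rate on noise-only profiles.
* `minIslandProbes` ($L$, default 5) — demands consistent evidence from
  several probes; single-probe excursions at aCGH noise levels are
  overwhelmingly artifacts.
* `direction` (`"both"`) — gains and losses are segmented by separate
  passes and merged; a probe can only support one direction.
* `minSpanBp` (0) — optional genomic-width floor, useful when probe
  spacing varies.

# Spurious-signal screening

`qcFlagSegments()` recomputes, from the probe data, each segment's block
statistics (`regionSummary()`: mean, median, extremes, sum, unbiased
variance) and attaches flags instead of deleting anything:

* `short` — fewer informative probes than `minProbes`;
* `weak` — $|$segmental mean$| <$ `minAbsSegmentalMean` (default 0.3,
  below the shift expected from a single-copy change in a diploid
  genome with tumor-fraction dilution);
* `noisy` — within-segment variance above `maxRegionVariance`
  (default 0.25); an optional outlier filter (`outlierLow`/`outlierHigh`)
  can first remove extreme probes, mimicking manual curation of hybridization
  artifacts.

Flags are additive and monotone: tightening any criterion can only add
flags. Downstream writers keep flagged segments by default
(`dropFailed = FALSE`) so that filtering decisions stay visible.

# Known/novel annotation

A segment is *known* if some catalogue record on the same chromosome
overlaps it by at least one base pair **and** the reciprocal overlap

$$\mathrm{RO} = \min\!\left(\frac{\mathrm{overlap}}{\mathrm{len}_{\text{segment}}},
\frac{\mathrm{overlap}}{\mathrm{len}_{\text{record}}}\right)$$

reaches `minReciprocal`; otherwise *novel*. RO is symmetric, and the
known set shrinks monotonically as `minReciprocal` grows. With
`matchType = TRUE` a `gain`/`loss` record supports only same-type
segments, while a generic `cnv` record matches either. The
implementation uses interval trees (`GenomicRanges::findOverlaps`); the
test suite checks it against an independent all-pairs quadratic scan.

# Sequencing cross-checks

`pileupColumns()` stacks aligned reads (Rsamtools/GenomicAlignments)
into per-position counts of A, C, G, T, N (all ambiguity codes pool
into N) and DEL (a deletion CIGAR operation spanning the position), with
`depth` equal to their sum — a conservation law asserted by the tests.
Reads can be excluded by SAM flag (unmapped, secondary, duplicate,
QC-fail by default) and by mapping quality; bases below `minBaseq` are
masked to N.

`callSnps()` reports a site when depth ≥ `minDepth` (default 5) and the
most frequent non-reference, non-deletion base reaches `minAltFraction`
(default 0.2) of the **total** depth — N and DEL dilute the fraction on
purpose, since they are evidence against a clean substitution. Ties
break by count, then alphabetically, making calls deterministic.

`depthDeletionScan()` reports maximal runs of positions whose *base*
depth (`depth − DEL`) is at or below `depthFloor`, at least `minSpan`
bp long. Base depth, not total depth, is the default because reads that
span a deletion junction place `D` operations across the entire deleted
interval: total depth inside a homozygous deletion stays near the
library average and would hide exactly the signal sought.

`compareSamples()` aligns two call sets by position and labels each
difference `only_a`, `only_b` or `allele_mismatch`; runs of at least
`windowSnps` consecutive differing sites (optionally distance-capped by
`maxGapBp`) become candidate regions, the multi-SNP analogue of a
discordant genotype block.

# Simulators: what they emulate and omit

`simulateAcgh()` lays probes at fixed spacing and adds rectangular
event shifts plus i.i.d. Gaussian noise. It emulates the first-order
signal model of aCGH (additive log-ratio shifts, probe-level noise) and
omits spatial autocorrelation, GC waves and dye bias — the segmentation
method does not model those either, so the simulator tests exactly what
the method claims.

`simulateReads()` draws a uniform-composition reference, excises an
optional homozygous deletion from the donor, places fixed-length
single-end reads uniformly on the donor, applies per-read planted-SNP
alleles (Bernoulli at the planted fraction) and uniform substitution
errors, and emits coordinate-sorted SAM. Reads crossing the deletion
junction get `aMdDbM` CIGARs, reproducing the D-operation depth
signature discussed above. Omitted on purpose: paired ends, indel
errors, quality-score variation, mapping ambiguity.

`makeAnnotationFixtures()` converts simulation truth into DGV/dbSNP-style
tables, with optional boundary jitter and decoy records that are
rejection-sampled to overlap no truth interval.

All three are pure functions of their arguments including `seed`
(implemented by saving and restoring `.Random.seed`), so identical
specifications yield byte-identical files — the basis of the
reproducibility guarantees in the test suite.

# Numerical and format conventions

* Coordinates are 1-based, closed intervals throughout (the native
  convention of `GRanges` and SAM); probe indices are 1-based.
* aCGH values are written with 12 significant digits, enough to
  round-trip doubles through text at the $10^{-9}$ tolerance the tests
  assert; segment statistics are written at 6 significant digits and
  re-writing a parsed file is byte-identical.
* Problem sizes used in validation (1,000 score vectors for the
  segmentation oracle, 100 seeds for recovery/specificity, 100 random
  SAMs for the pileup oracle, 20 seeds for the deletion scan, and so
  on) are this package's own choices, scaled to finish comfortably
  within a few minutes on one CPU while keeping binomial noise on the
  reported percentages small.

# A worked pipeline

```{r pipeline}
sim <- simulateAcgh(c(chr1 = 120), noiseSd = 0.15,
                    events = data.frame(chrom = "chr1", first_probe = 50,
                                        last_probe = 59, delta = 1),
                    seed = 1)
segs <- detectAll(sim$acgh, CnvParams(madMultiplier = 3,
                                      minIslandProbes = 5))
segs <- qcFlagSegments(segs, sim$acgh, QcCriteria())
fx <- makeAnnotationFixtures(
  data.frame(chrom = "chr1", start = sim$truth$start,
             end = sim$truth$end, type = "gain"),
  NULL, c(chr1 = 700000L), seed = 2)
dgvFile <- tempfile()
writeAnnotationFixtures(fx, dgvFile = dgvFile)
annotateSegments(segs, readDgv(dgvFile))$segments
```

The same pipeline is exposed verb-by-verb on the command line
(`simulate`, `detect`, `qc`, `annotate`, `depth`, `call`, `compare`,
`matrix`) through the `swcnv` script installed under
`system.file("scripts", "swcnv", package = "swcnv")`; every output is
written atomically next to a JSON manifest that records the effective
parameters and input/output paths of the run.
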