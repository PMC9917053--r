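---
title: "Per-gene differential analysis of purified eccDNA: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-gene differential analysis of purified eccDNA: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difcir)
```

This vignette explains the model behind the package, the parameters that
matter and why they default as they do, the behaviour of the synthetic-data
generator, and the numerical and design choices made where the procedure
left genuine freedom.

## Signal model

Purified-eccDNA sequencing (Circle-Seq and kin) yields, after an external
split-read caller, a table of circular junctions per sample: an interval on
the reference and the number of **split reads** supporting the junction.
The split-read count is the quantitative unit throughout: the working
assumption is that many cells in a tissue sample can excise circles from
the same locus, so the split-read count behaves as a copy-number-like
measure of how actively a locus *produces* circles — not merely whether a
unique circle species was detected. This is the essential difference from
analyses that count unique circles per gene: a gene shedding the same
circle in many cells counts strongly here, and genes shedding long circles
are not favoured, because a junction contributes the same signal whatever
the circle's length.

## Processing cascade

Three per-sample steps precede quantification, with thresholds applied
strictly as worded:

* **Length/chromosome filter.** Circles with length > `l_max`
  (default 100,000 bp) are removed — boundary kept — as are mitochondrial
  circles. Mitochondrial calls are retained separately: since interval
  merging collapses the whole ~16.6 kb mitochondrial genome into one
  "unique circle", the per-sample mitochondrial signal is instead the sum
  of raw split reads on the mitochondrial chromosome, taken before any
  merging or support filtering.
* **Junction merging.** Two calls are linked when both endpoint
  differences are strictly below `d_min` (default 10 bp) on the same
  chromosome; clusters are connected components (transitive closure) and
  collapse to (min start, max end) with split reads summed. Linkage uses
  *both endpoints* rather than interval overlap: the merged entities are
  junctions, and overlap-based merging would collapse distinct circles that
  happen to share one breakpoint. Calls at endpoint distance exactly
  `d_min` do not link.
* **Support filter.** Merged circles with fewer than `jt_min` (default 2)
  split reads are dropped; the boundary is kept. Because this runs after
  merging, two weakly supported near-duplicate calls can survive through
  their summed support — the intended behaviour for PCR/mapping jitter
  around one true junction.

## Quantification: PpGC, scaling, equalization

A circle is attributed to every gene whose *body* it overlaps by at least
1 bp (half-open intervals; adjacency is not overlap). Gene-body rather
than exon overlap is used because a circle carrying any fragment of a gene
is evidence of production from that gene. A multi-gene circle counts fully
toward each overlapped gene; no split-read apportioning is attempted,
matching default intersection semantics, and the choice is isolated in
`annotate_circles()` should a user want to change it.

The raw PpGC matrix (genes × samples) holds per-gene split-read sums.
Longer genes intercept more circles, so each gene's row is scaled by
`L_Max / L_i`, with `L_i` the gene-body length and `L_Max` the longest
gene *found in the dataset* (genes with at least one circle anywhere); a
flag switches `L_Max` to the annotation-wide longest gene. Gene length
means body length from the annotation, not summed exon length. Finally
values are equalized as log2(x + 1), the scale on which all group
statistics operate.

## Differential calling

Per gene, the group means of equalized values are compared: the log2 fold
change is their difference (computed after the +1 log transform, so it is
a difference of stabilized means, not a ratio of raw counts), and the
p-value comes from a two-sided two-sample Student's t-test with pooled
variance — the classical test, with Welch's correction available behind a
flag but off by default. A gene is an up-DPpGC in a group when its
|log2FC| ≥ `theta` (default 1) *toward that group* and p ≤ `alpha`
(default 0.05). Raw p-values are the default, reflecting how such
selections are usually reported for this data type; Benjamini–Hochberg
adjustment is available behind a flag and then gates the selection.

Degenerate rows follow the limits of the t statistic: when both group
variances are zero, p is 1 for equal means and 0 otherwise. Significant
records are ranked within each direction by p ascending, then |log2FC|
descending, then gene id — a total order, so reruns are reproducible.

One wording issue deserves a note: the selection rule is sometimes stated
as keeping genes whose mean difference is *less than* the threshold, which
would select the null rather than the signal and contradicts how volcano
plots of such selections are drawn. The implementation reads the rule as
|Δmean| ≥ θ.

The scaled and unscaled analyses share one code path (the unscaled variant
simply skips the scale factor), and `compare_scaling_ranks()` reports, per
significant gene, the rank under each variant and the membership
(both/scaled-only/unscaled-only). `length_bias_regression()` fits
−log10(p) against gene length over the significant calls by ordinary least
squares; a near-zero slope and R² indicate scaling did not introduce a
length bias into the ranking.

## Democratic voting

To characterize one group without a comparison group, each sample votes
for every gene whose equalized PpGC reaches a threshold, and genes with at
least `min_votes` (default 4) votes are the group's Common PpGCs. The
threshold is data-derived: pool all *nonzero* equalized values of the
group, histogram them at `bin_width` 0.5, smooth, and take the floor of
the center of the highest bin — the floor of the distribution's mode.
Design choices here, and why:

* **Equalized scale, zeros excluded.** On the raw scale a mode-based
  threshold would sit implausibly low; on the equalized scale a threshold
  of ~6 corresponds to ~64 split-read equivalents, the magnitude at which
  consistent producers separate from noise. Zeros are excluded because a
  zero-inflated mode would pin the threshold at 0 and make voting vacuous.
* **Mode location, not density value.** "Floor of the maximum of the
  distribution" is read as the *position* of the density maximum, the
  quantity a threshold on values must be.
* **Mode-preserving smoothing.** The histogram is smoothed with a
  *centered triangular-weighted* window (1–2–1 over 3 bins by default). A
  uniform moving average would flatten an isolated single-bin mode into a
  plateau and shift the argmax one bin left under the leftmost-tie rule;
  the triangular kernel keeps a lone spike at its own bin while still
  damping bin noise. Ties go to the leftmost bin — the conservative
  (lower-threshold) choice.
* **Inclusive comparison.** A value equal to the threshold counts as a
  vote ("at least"); a strict mode is available.

Both `bin_width` and the smoothing window are configurable; the defaults
(0.5 on the log2 scale, 3 bins) resolve modes to half a log2 unit, which
is as fine as n = 8 samples of pooled per-gene values can support.

## Whole-gene detection

A sample carries gene *g* whole when any single processed circle satisfies
start ≤ g.start and end ≥ g.end on the same chromosome — inclusive at both
ends, so a circle with exactly the gene's coordinates counts. Containment
by a single circle is required (a merged cluster spanning the gene via
chaining does not count unless its collapsed interval does). Genes carried
in at least `min_samples` (default 2) samples are reported, alongside a
0/1 gene × sample presence matrix with 1 = present.

## The synthetic-data generator

`simulate_eccdna()` emulates the *structure* of processed two-group
Circle-Seq data: per-gene circle production (Poisson counts per gene and
sample, multiplicative group effects on spiked genes), shifted-geometric
split-read support (minimum 1, default mean 2), circle lengths from a
nucleosome-periodic mixture (peaks at 160/320/480 bp plus an exponential
tail), intergenic noise circles, mitochondrial calls, jittered
near-duplicate junctions (jitter < `d_min`) that exercise the merge, and
occasional circles containing a whole gene.

Its defaults are calibrated against the descriptive statistics of purified
skeletal-muscle eccDNA studies: with 120 genes and `baseline_rate = 20`
circles per gene per sample, a sample carries on the order of 2,000–3,000
unique circles after processing, and the mode of a group's scaled,
equalized PpGC distribution lands near 6 — the magnitude at which the
democratic threshold operates on real data. Two groups of 8 samples match
the cohort size such studies use.

A deliberate construction makes ground truth exact rather than
approximate: circle start positions are laid on a grid of spacing
2·`d_min`, so two distinct circles can never satisfy the both-endpoint
linkage rule, while a near-duplicate (jitter strictly below `d_min`)
always merges back onto its parent and only its parent. Intergenic noise
circles use the same grid offset by `d_min`, which keeps them unlinkable
to genic circles as well. The generator can therefore book-keep the exact
per-gene split-read totals the pipeline must recover — including the
effect of the support filter on merged duplicates — and the test suite
checks the recovery cell-for-cell.

What the generator does **not** emulate: library-preparation and
amplification biases, sequencing-depth differences between samples,
mapping ambiguity, chimeric artifacts, or sequence content of any kind.
Tests passing on simulated data therefore validate the downstream
arithmetic — filtering, merging, attribution, scaling, testing, voting —
not robustness to those upstream effects.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; GTF input is converted
  at the boundary, and a flag converts 1-based circle-call tables.
  Strand is ignored throughout: junctions are unstranded observations.
* The merge representative is (min start, max end) of the cluster —
  standard interval-union semantics.
* Merging is order-invariant (sorted processing plus canonical output
  order) and idempotent except for genuine chain-merging, where collapsed
  representatives of separate clusters move within linking range; the
  tests detect and verify rather than hide those cases.
* Rank-sum comparisons of descriptive quantities use the exact null
  distribution for small tie-free samples and the tie-corrected normal
  approximation with continuity correction otherwise.
* Result tables are written at full precision and round-trip exactly
  through the package's readers.
* Empty inputs (no calls, header-only files, all-zero tables) return
  empty results or a specific error, never a crash; an all-zero vote table
  is an error because no threshold exists.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data:
oracle comparisons use 200 random instances of up to 100 calls; t-test
accuracy uses 1,000 random gene rows against the closed-form pooled
reference; null calibration uses 2,000 genes at n = 8 per group; spike
recovery uses 20 genes at 4× production per group in the default
120-gene, 2 × 8-sample simulation. These sizes make every check rerun in
seconds while keeping the group sizes and effect structure of the study
design they emulate.

## Known limitations

* Attribution of multi-gene circles is all-or-nothing per gene; dense gene
  clusters can double-count junctions across neighbours.
* `L_Max` depends on the dataset (unless taken from the annotation), so
  scaled values are not directly comparable across datasets with different
  gene universes.
* The pooled t-test assumes comparable within-group variances on the
  equalized scale; the Welch flag exists for datasets where that fails.
* The democratic threshold is a group-level scalar; samples with very
  different sequencing depths shift the pooled distribution and thus the
  threshold. No depth normalization is attempted because split-read totals
  are the unit of the method.
* No significance is attached to CPpGCs — they are descriptive consensus
  calls, complementary to the differential test.
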