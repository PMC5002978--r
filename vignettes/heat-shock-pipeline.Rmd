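---
title: "Methods: PRO-seq heat-shock analysis with proseqhs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRO-seq heat-shock analysis with proseqhs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proseqhs)
```

## The data and the coordinate contract

PRO-seq records, strand-specifically and at base resolution, the 3′ end
of the nascent RNA in every transcriptionally engaged polymerase. The
package consumes these as one plus- and one minus-strand bedGraph per
library, held in a `signal_track`: a sparse map from (chromosome,
strand, position) to a read count. Every coordinate in the package is
0-based half-open — bedGraph and BED are consumed natively, and a
window phrased as "−500 to −100 bp of the TSS" is the half-open
relative window [−500, −100) of length 400. Relative offset *r* maps
to genomic position TSS + *r* on the plus strand and TSS − *r* on the
minus strand. One stated convention removes every boundary ambiguity;
the mirror-invariance property test (reflect the genome, flip all
strands, counts unchanged) guards it.

Windows that would extend beyond a chromosome are clipped, with the
mappable-base denominator reflecting the clip. When no mappability
track is supplied, every position counts as mappable — correct for the
synthetic data; real data can pass mappability intervals anywhere a
density is computed.

## Normalization by an invariant gene set

Heat shock changes transcription genome-wide, so total read counts
carry real biology and cannot serve as size factors. Instead the
package selects genes whose transcription does not change, with three
filters applied in order:

1. **Antisense filter** — the fraction of reads on the antisense strand
   over the gene span must be ≤ 0.2 in both control conditions, so the
   sense signal dominates (ChIP signal is unstranded; PRO-seq is not).
2. **ChIP filter** — the z-score of the elongating-polymerase
   (Ser2-P-style) ChIP signal must exceed 3, restricting to genes whose
   transcription clearly exceeds ChIP background. The z-score is
   computed on the log10 signal by default (`zscore_transform`): the
   untransformed signal is so heavy-tailed that a raw z-score ranks
   genes by a few extreme values. Either transform is selectable.
3. **Stability filter** — the HS/NHS gene-body fold change must lie in
   [0.85, 1.15].

A subtlety in filter 3: raw fold changes are confounded by sequencing
depth, and total-read scaling re-introduces the genome-wide shift the
method exists to avoid (in the synthetic study conditions, HS libraries
carry ~20% more body signal per unit depth, which would push every
truly unchanged gene's apparent fold change to ~0.85 and empty the
window). The package therefore anchors each candidate's depth-scaled
fold change at the median fold change of the genes that already passed
filters 1–2 — a pool dominated by invariant genes by construction —
and applies the window to the anchored value. `fc_scale = "raw"`
recovers the literal raw-count behavior for depth-matched libraries.

Size factors are then *S*~ℓ~/geomean(*S*), with *S*~ℓ~ the raw summed
gene-body reads of library ℓ over the invariant set. Anchoring the
geometric mean at 1 is a convention; all ratios — the quantities that
matter — are anchor-invariant, which is tested as a property.

## The differential test

Gene-body reads are collected from 200 bp downstream of the TSS (past
the promoter-proximal pause) to the annotated end, capped for a
*t*-minute heat-shock contrast at 1000·*t* bp (a conservative 1 kb/min
elongation rate: signal further 3′ cannot yet have responded). The same
capped window is used for both conditions of a contrast so counts are
comparable; genes whose capped window is empty are excluded with a
reason code.

The test itself is a deliberately simple DESeq2-style negative-binomial
Wald test, authored in the package:

- per-gene dispersion by method of moments,
  α̂ = max(10⁻⁸, (v − m)/m²), with *v* the pooled within-condition
  variance of size-factor-normalized counts (n − k degrees of freedom)
  and *m* their grand mean;
- log2 fold change from the ratio of condition means of normalized
  counts, with a 0.5 pseudocount only when a mean is zero;
- a delta-method standard error from the NB variance of each condition
  mean, and a two-sided p-value from the normal reference.

With two replicates per condition a per-gene 2-df dispersion plug-in
makes the normal-reference Wald statistic strongly anti-conservative
(the statistic is effectively *t*-distributed with ~2 df), so the
default pools the dispersion across genes — the mean of the per-gene
moment estimates — before computing standard errors
(`dispersion = "per_gene"` keeps the plug-in). The all-null calibration
test and the FDR properties in the acceptance suite validate this
choice under the study conditions, where a single dispersion generates
every gene. On real data with gene-specific overdispersion the pooled
default is optimistic for the most dispersed genes; that is the main
statistical simplification relative to a shrinkage estimator, and it is
deliberate — no dispersion trend, no LFC shrinkage, no outlier
filtering — so every number is traceable to a formula above.

The Wald p-value is asymptotic: against the exact conditional
(binomial) test in the Poisson limit it agrees to within 0.02 once
window counts reach roughly 100 reads, and deviates more below ~50
reads. Benjamini–Hochberg adjustment is an explicit step-up (tested
against an independent implementation exactly). Classes at FDR 0.001:
activated (padj ≤ 0.001, lfc > 0), repressed (padj ≤ 0.001, lfc < 0);
unchanged requires padj > 0.5 **and** −0.25 < lfc < 0.25; everything
else is ambiguous, a deliberate buffer class rather than a forced call.

## The run-through filter

A gene downstream of a strongly induced neighbor can inherit that
neighbor's read-through transcription and masquerade as activated. The
upstream ratio — mappability-adjusted sense density in [−500, −100)
over density in [+300, +700) — flags this: genuine activation has
little signal upstream of its own TSS, run-through has more upstream
than in the body (the signal decays with distance). The upstream
window stops 100 bp short of the TSS to dodge misannotated starts; the
body window starts at +300 to clear the pause peak.

Genes with ratio > 0.23 (strict inequality; 0.23 retained) are removed
from the activated class using the HS ratio and from the repressed
class using the NHS ratio — in each case the condition with more
signal, hence the better-measured ratio. Genes with an undefined ratio
(zero body density) are retained and flagged rather than silently
dropped. The grid search behind the cutoff evaluates accuracy
((true retained + false removed)/total) over cutoffs 0 to 1 in 0.01
steps against a labeled set; ties break to the smallest cutoff — the
most stringent filter — since nothing else distinguishes tied optima.
The shipped default stays 0.23. On synthetic data the labels come from
the generator's truth table, standing in for the manual genome-browser
curation such label sets otherwise require.

## Pausing

The pause region is the 50-bp window with the most reads among all
1-bp-stepped candidates in [−50, +150) around the TSS, detected once in
the pooled control NHS track and reused for every treatment so that
between-condition comparisons are over identical coordinates. Ties
break to the most upstream start (so an all-zero gene deterministically
gets [−50, 0)); the detector is tested for exact equality against an
exhaustive scan.

The pausing index is pause-region read density over gene-body density
(both reads per mappable base; the body window is the differential
stage's definition). It is undefined — and the gene excluded from PI
comparisons — when the body density is zero. The paused call is a
one-sided Fisher's exact test on the 2×2 table contrasting reads
(pause, body) against mappable bases (pause, body), i.e. read counts
against positional opportunity, with paused ⇔ p ≤ 0.01. The table
construction is the package's own explicit definition of the widely
used classifier; it is conservative under uniform density (the
null rate is checked in the acceptance suite) and exact-equal to a
hypergeometric tail sum. Pausing-level changes between conditions reuse
the NB Wald machinery on pause-window counts at FDR 0.001, with windows
fixed from the reference condition.

## Composite profiles and heat maps

Signal matrices bin sense-strand reads in TSS-relative windows
(orientation-flipped for minus-strand genes so bin 1 is always most
upstream), normalized by the library size factor. A composite profile
draws 1000 subsamples of 10% of the genes **without replacement**
(with-replacement resampling is the configurable alternative; without
was adopted as the plain reading of "subsampling"), records each
subsample's per-bin mean, and reports the per-bin median of those means
with the central 75% interval (12.5th/87.75th percentiles) as the band.
The per-subsample statistic being the mean — and the median taken
across subsamples — makes the composite robust to a handful of extreme
genes without discarding them. Genes are canonically sorted by id
before the seeded subsampling, so the result is independent of input
row order; a fixed seed gives bit-identical output. Heat-map matrices
order genes by |distance of the maximal bin from the TSS| (pausing
displays) or by a supplied per-gene value, highest first (fold-change
displays), with gene-id tie-breaks for determinism.

## TF binding statistics

The closest-peak distance is 0 when the TSS lies inside a peak and
otherwise the gap to the nearest peak edge (half-open intervals),
signed by transcription direction — positive downstream of the TSS —
matching closest-interval semantics of the standard interval tools. A
gene is bound when |distance| ≤ 1000 bp (inclusive). Distance
distributions between gene classes are compared with a two-sample KS
test on absolute distances; the promoter-signal enrichment screen runs
a two-sided Mann–Whitney U per factor on a [−750, +750) promoter
window (the display-profile extent; configurable, as the screen's exact
window is a free choice), ranking factors by ascending p with the sign
of the median difference as direction. Genes on peak-free chromosomes
report a missing distance, never an infinite one.

## The synthetic-data generator

The generator is first-class, tested code defining the study
conditions. Per gene it deposits:

- a pause peak of 3′ ends at offsets +20..+60, discretized-triangular
  with mode +35 (the canonical 20–60 bp pause zone), expected
  `pause_reads` ∈ [50, 300] per gene at depth 1;
- a uniform gene body over [TSS+200, end) at `body_rate` ∈ [50, 200]
  reads/kb, multiplied under HS by the gene's true fold change only
  within the elongation front [TSS+200, TSS+1000·t);
- uniform antisense background at 2 reads/kb on the opposite strand;
- for run-through victims, the upstream source's body signal continuing
  past the source's 3′ end with per-bp geometric decay 0.9997
  (half-distance ≈ 2.3 kb) across the gap and through the victim. A
  victim is placed immediately downstream of an activated source on the
  plus strand, so its apparent induction is pure artifact — the false
  positive the upstream filter exists to remove.

All counts are negative-binomial with variance m + αm², the same
parameterization the test inverts, so parameter recovery is
well-posed. The default dispersion is α = 0.005 (a ~7% CV above
Poisson), reflecting the tightly correlated replicate libraries of
cultured-cell PRO-seq (replicate rank correlations in the 0.96–0.99
range); the calibration scenario overrides it to α = 0.05 to stress
the test. Default classes: 5% activated at 8-fold, 15% repressed at
3-fold — the effect sizes of the recovery study — with per-library
depth factors (1.0, 1.3, 0.8, 1.1) and a 20-minute heat shock. The
ChIP signal is a broad lognormal bulk with a well-separated high mode
(300×, 5% of genes) placed on unchanged genes, emulating the strongly
right-skewed elongating-Pol II ChIP distribution whose top tail the
z > 3 filter selects and the fact that constitutively high, stable
transcription is what makes a gene a usable normalization anchor.

One global seed drives everything; per-library streams are derived by
fixed offsets, so callers never book-keep seeds and all outputs are
bit-reproducible.

What the generator does **not** emulate: mappability holes (synthetic
genomes are fully mappable; the mappability plumbing is exercised by
unit tests instead), enhancer and intergenic transcription, misannotated
TSSs, gene-specific dispersion, base-composition or library-prep
biases, and divergent-promoter architecture beyond a flat antisense
rate. Passing tests therefore demonstrate the correctness and
calibration of the *procedures* under the stated generative model, not
robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The shipped study scenario uses 2000 genes on two 6.5-Mb chromosomes
and four libraries (~1.5–2M reads each), sized so the full pipeline,
the test suite and the validation script each run in minutes on one
CPU while keeping ≥ 300 genes in every class of interest. Window sums
use a per-(chromosome, strand) cumulative-count index with an O(log n)
binary search per window edge. Degenerate inputs are handled
explicitly: empty tracks count zero everywhere, all-zero genes are
excluded from dispersion estimation with NA results, zero-variance
z-scoring and empty invariant sets raise errors that name the remedy,
and Fisher tables with no reads return p = 1.

## Known limitations

- The NB test's pooled dispersion and asymptotic p-values are
  simplifications; genes with < ~50 body reads or atypical dispersion
  deserve a shrinkage-based reanalysis on real data.
- The paused classification contrasts reads with mappable-base
  opportunity; other classifiers in use contrast pause reads with a
  matched body-read expectation, and the two disagree at extreme
  body densities.
- Multi-factor designs and time-course models are out of scope: each
  time point is a separate two-condition contrast against NHS.
- BAM/SAM and bigWig inputs are not parsed; the pipeline starts from
  bedGraph 3′-end histograms.
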