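# proseqhs

Genome-wide analysis of nascent transcription during heat shock, from
strand-specific base-resolution PRO-seq 3′-end tracks.

PRO-seq maps the active site of every transcriptionally engaged RNA
polymerase at single-base, strand-specific resolution. During heat shock
(HS) transcription changes genome-wide, so total read counts cannot
normalize libraries between conditions, apparent activation can be an
artifact of run-through transcription from an upstream gene, and the key
regulatory step — release of promoter-proximally paused Pol II into the
gene body — has to be quantified from windowed read densities. `proseqhs`
implements that full analysis as a tested R package:

- **Invariant-gene normalization.** Candidate genes must have an antisense
  read fraction ≤ 0.2 in both conditions, an elongating-Pol II (Ser2-P
  style) ChIP z-score > 3, and an HS/NHS gene-body fold change inside
  [0.85, 1.15]. Library *ℓ*'s size factor is
  *S<sub>ℓ</sub>* / geomean(*S*), where *S<sub>ℓ</sub>* is its summed
  gene-body reads over the invariant set.
- **Differential transcription.** Gene-body reads are counted in
  [TSS+200, min(*L*, 1000·*t*)) for a *t*-minute time point (1 kb/min
  elongation cap) and tested with a negative-binomial Wald test
  (method-of-moments dispersion pooled across genes, externally supplied
  size factors), Benjamini–Hochberg adjusted. Classes at FDR 0.001:
  activated (lfc > 0), repressed (lfc < 0); unchanged requires
  padj > 0.5 and |log₂ fc| < 0.25.
- **Run-through filter.** The *upstream ratio* is the mappability-adjusted
  sense density in [−500, −100) over the density in [+300, +700);
  genes with ratio > 0.23 are dropped from the activated (HS ratio) or
  repressed (NHS ratio) classes. The cutoff's accuracy-maximizing grid
  search over 0–1 in 0.01 steps is included.
- **Pausing.** The pause region is the maximal-count 50-bp window in
  [−50, +150) fixed from the control NHS data; the pausing index is
  pause density over body density; paused genes have a one-sided Fisher's
  exact *p* ≤ 0.01 (reads vs mappable-base opportunity), and pausing
  changes are tested with the same NB machinery at FDR 0.001.
- **Composite profiles.** Per-class metagene profiles are the per-bin
  median of 1000 subsample means (10% of genes each) with a central 75%
  band; heat-map matrices order genes by pause-peak distance or fold
  change.
- **TF binding.** Signed closest-peak-to-TSS distances, bound calls
  within ±1 kb, Kolmogorov–Smirnov distance-distribution comparisons and
  a Mann–Whitney promoter-signal enrichment screen.
- **Synthetic data with ground truth.** A generator that emulates paused
  genes (3′-end peak 20–60 bp downstream of the TSS), uniform gene
  bodies, antisense background, per-library depth factors,
  elongation-limited HS effects and run-through bleeding into downstream
  genes — so every stage is validated against known truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # tracks, genes, truth, peaks
Rscript analysis/02_normalize.R       # invariant set + size factors
Rscript analysis/03_differential.R    # NB test + classes at FDR 0.001
Rscript analysis/04_runthrough_filter.R
Rscript analysis/05_pausing.R
Rscript analysis/06_profiles.R
Rscript analysis/07_tf_binding.R
```

Output from a run (seed 1; two NHS and two 20-min-HS libraries at true
depth factors 1.0, 1.3, 0.8, 1.1):

```
Invariant set: 91 of 2000 genes pass all three filters
Size factors: lib1 0.9574 lib2 1.2753 lib3 0.7804 lib4 1.0496

Recall: activated 100.0%, repressed 100.0%
Empirical FDR (excluding run-through victims): 0.00%
Run-through victims currently misclassified as activated: 20 (handled by stage 04)

Cutoff search: best accuracy 1.000 at cutoff 0.00 (shipped default 0.23)
Removed 20/20 run-through artifacts; lost 0/100 true activated genes

Paused in NHS: 100.0% of all genes
  activated: 100.0% paused, median PI 25.4

NHS / activated: 100 genes, peak median 89.30 at 37.5 bp
Bound genes (peak within 1 kb of TSS): 125 of 2000
  activated: 90.0% bound; unchanged: 2.1% bound
KS test activated vs unchanged distances: D = 0.899, p = 0
```

The size factors recover the simulated depth ratios to within ~2%, all
8-fold-activated and 3-fold-repressed genes are found at FDR 0.001, the
composite pause peak sits at +37.5 bp (the generator places it at +35),
and the upstream-ratio filter removes every run-through artifact without
losing true activated genes.

The same computations are available programmatically:

```r
library(proseqhs)
sc <- generate_scenario(scenario_config(seed = 1))
ex <- simulate_experiment(sc)
res <- run_pipeline(ex$tracks, ex$design, sc$genes, sc$truth$chip_signal)
res$report$classes_post_filter
```

Real data enter through `read_bedgraph_pair()` (one plus- and one
minus-strand bedGraph per library), `read_genes()` (BED6, one
transcription unit per gene) and `read_intervals()` (mappability, peaks).
All coordinates are 0-based half-open throughout.

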