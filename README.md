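# evnet — enhancer–variant integration and regulatory genomics toolkit

Most GWAS hits land in non-coding DNA, leaving open which cell lineage
carries the association. `evnet` implements the standard integrative
answer for bone-density-style traits: overlay the variant panel on
**lineage-specific active enhancers** — H3K27Ac ChIP-seq regions
partitioned by whether they contain a peak of the lineage's master
transcription factor (e.g. PU.1 in the osteoclast/myeloid compartment,
RUNX2 in the osteoblast/mesenchymal compartment) — then assign candidate
target genes by nearest TSS, test the gene lists for functional
enrichment, and profile TF binding-motif density around the variants.
Superenhancer calling and a cross-species comparison of TF expression
kinetics round out the workflow. A first-class synthetic-data module
generates every input with known ground truth, so the whole pipeline is
validated end to end by recovery and calibration experiments.

## The statistics at the core

* **Enhancer partition / SNP overlay.** Enhancer *e* is bound iff
  `|e ∩ p| ≥ 1 bp` for some TF peak *p*; SNP *s* lies in *e* iff
  `start ≤ pos < end` (0-based half-open throughout). A variant passes
  filtering iff `P ≤ α` (inclusive, default 0.05) in ≥ 1 of the six
  association groups ({femoral neck, lumbar spine} × {men, women,
  pooled}).
* **Density contrast.** 2×2 table of (unique SNPs, non-SNP bp) by
  class; odds ratio + Fisher's exact P.
* **Motif density.** Log2-odds PWM scan
  `s(w) = Σ_j log2(p_j(w_j)/bg(w_j))`; hits binned by motif-window
  center relative to the SNP; density per SNP per bp; central-core
  (150 bp) enrichment vs the non-bound-class background with an exact
  binomial test.
* **Set enrichment.** Exact hypergeometric upper tail
  `P(X ≥ k)` (log-space sum) with Benjamini–Hochberg correction; GSEA
  as the weighted Kolmogorov–Smirnov running sum with gene-set
  permutation, `NES = ES / mean |ES_null, same sign|`, NES-pooled FDR.
* **Superenhancers.** Stitch peaks with gaps ≤ 12.5 kb, rank stitched
  regions by tag signal, scale rank and signal to the unit square, cut
  where a slope-1 line is tangent to the curve (argmin of `y − x`);
  calls are the suffix strictly above the cutoff.
* **Kinetics.** Cross-species concordance as Pearson *r* between time
  profiles (retain `r ≥ 0.5`); centered K-means (1 − Pearson on
  mean-centered rows) over the concatenated 8-sample course;
  `2^−ΔΔCt` fold changes for qPCR.

## Worked example

The packaged demo configuration simulates a study (600 enhancers, 40%
TF-bound, 4 000 SNPs at 3× density in bound enhancers, planted motif
instances, 5 planted superenhancer loci, 75/200 concordant TFs) and runs
every analysis stage on the emitted files:

```r
library(evnet)
run_config(system.file("extdata/demo_config.yaml", package = "evnet"),
           "demo_out")
```

`demo_out/report.txt` then reads:

```
evnet run report
seed: 20260929

[integration]
  enhancers: 240 bound / 360 non-bound of 600
  unique SNPs: 365 in bound, 178 in non-bound enhancers
  bound-class genes: 109; density odds ratio 3.12 (Fisher P 4.54e-38)

[motif density]
  central-core hit mass (bound class): 0.94
  bound/non-bound core density ratio: 108.41

[gene-set enrichment]
  top set SET_05: k=22/25, P=0.0447, q=0.447

[GSEA]
  top set SET_09: ES=0.71, NES=1.73, P=0.00351

[superenhancers]
  268 stitched regions, 10 called super

[kinetics]
  75 orthologs retained as kinetically concordant
```

Reading the numbers: the partition recovers the constructed 40% bound
fraction exactly (240/600); the odds ratio estimates the planted 3×
SNP-density enrichment; 94% of motif hits around bound-class lead SNPs
fall in the central 150 bp, against an essentially flat non-bound
background; the 5 planted high-signal loci rank first among 268
stitched regions (the cutoff admits a handful of strong background
regions, as rank-signal cutoffs do); and the concordance filter
retains exactly the 75 planted conserved TFs. Per-stage tables (BEDs,
TSVs, JSON summaries) and a manifest with per-file checksums land next
to the report; rerunning with the same config and seed reproduces every
data file byte for byte.

A thin CLI wraps the same entry point:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/evnet.R", package="evnet"))')" \
  all --config run.yaml --outdir out --seed 1
```

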