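---
title: "Integrating GWAS variants with lineage-specific enhancer landscapes"
author: "evnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating GWAS variants with lineage-specific enhancer landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

Genome-wide association studies locate trait-associated SNPs, but most
hits fall in non-coding DNA and say nothing by themselves about *which
cell lineage* mediates the association. One productive strategy is to
intersect the variant panel with lineage-specific regulatory maps: define
the active enhancers of a lineage from histone-mark ChIP-seq (H3K27Ac),
mark the subset bound by the lineage's master transcription factor (TF)
from TF ChIP-seq peaks, and ask whether trait SNPs preferentially fall in
TF-bound enhancers. SNP-bearing enhancers are then tied to candidate
target genes by nearest-TSS assignment, and the resulting gene lists are
interrogated by set enrichment. Around the SNPs themselves, binding-motif
density profiles test whether the variants sit near the TF's sequence
elements. Two satellite analyses complete the picture: superenhancer
calling (clusters of closely spaced, exceptionally strong peaks, found by
stitching and a rank-signal cutoff) and a cross-species comparison of TF
expression kinetics during differentiation, which flags regulators whose
temporal programs are conserved.

`evnet` implements this entire workflow as composable R functions, and —
because the real inputs (consortium GWAS summary statistics, archived
ChIP-seq peak calls) are not redistributable — ships a synthetic-data
module that generates every input with known ground truth. All
quantitative claims made by the test suite are recovery or calibration
statements on those synthetic inputs.

## Coordinate conventions

All interval containers are 0-based half-open (BED-native). GTF input
(1-based inclusive) and GWAS SNP tables (1-based positions) are converted
at the boundary, so overlap arithmetic has a single convention:
intervals sharing only a boundary coordinate do not overlap, and a SNP at
position `p` is inside `[start, end)` iff `start <= p < end`. Strand is
ignored for all intersections; it matters only for gene anatomy (TSS/TTS
orientation, signed distances) and for collapsing sequencing tags to 5'
ends. The minus-strand TSS is the half-open *end* of the last exon.
Chromosome names are matched by exact string equality.

## The integration model

An H3K27Ac region is **bound** iff it shares at least one bp with at
least one TF peak (`partition_enhancers_by_tf()`). A filtered variant
passes when its association P-value is at or below `alpha` (inclusive,
default 0.05) in **at least one** of the six association groups
(femoral-neck / lumbar-spine density for men / women / pooled samples);
a configuration switch (`all_groups`) demands all selected groups
instead, since the pooling rule used upstream of such panels is usually
not recoverable. SNPs hitting both a bound and a non-bound enhancer
(possible when enhancer calls overlap) are credited to the bound class
and flagged, keeping the two classes disjoint for counting.

The bound/non-bound contrast is quantified as a 2x2 table of (unique
SNPs, non-SNP bp) by class — enhancer base pairs act as exposure — with a
sample odds ratio and Fisher's exact P (`bound_vs_unbound_enrichment()`).
Under density enrichment `f` planted by the generator, the odds ratio
estimates `f` because SNP counts are small relative to exposure bp.

`peaks_near_snps()` retains a TF peak when a passing SNP lies within
`[start - w, end + w)` for window `w` (default 500 bp): distance is
measured from the SNP point to the nearest peak bp, with the extension
half-open on the right.

### Calibration problem sizes

Fisher's exact test is conservative on coarse support: with only a few
hundred passing SNPs per class the hypergeometric point masses are
~0.03-0.07 wide, and the null P distribution is visibly
super-uniform — a property of any exact test at that granularity, not of
the pipeline. The null-calibration experiments therefore use replicate
panels of 8 000 SNPs (~2 100 passing), where the support is fine enough
that a Kolmogorov-Smirnov test against U(0,1) over 200 replicates does
not reject at alpha 0.01.

## Nearest-TSS gene assignment and peak annotation

`nearest_tss()` assigns the same-chromosome gene minimizing |position -
TSS|, with ties broken by the lexicographically smallest gene id, so
assignment is deterministic. Signed distances are reported relative to
gene orientation (negative upstream). Peak annotation
(`annotate_peaks()`) categorizes the peak **center** with precedence
promoter-TSS > TTS > 5'UTR > 3'UTR > exon > intron > intergenic; the
promoter and TTS windows default to +/-1000 bp and are configurable —
annotation-tool defaults, since no single window is canonical. UTR
categories require CDS coordinates (refFlat input); GTF input without
CDS features reports exonic centers as `exon`.

## Motif scanning and positional density

A PWM is scored as a log2-odds sum `s(w) = sum_j log2(p_j(w_j) /
bg(w_j))`. Counts become probabilities with a JASPAR-style pseudocount
(default 0.8, distributed by the background). The default hit threshold
is 60% of the maximum achievable score — scanning tools do not agree on a
canonical threshold, so it is exposed and stated in output. The reverse
strand is scored on the reverse complement and reported at
forward-strand coordinates; windows containing N are skipped. Hits are
binned by the **center** of the motif window, which removes
length-dependent asymmetry from profiles; density is normalized per
anchoring position per bp. Central-core enrichment (default core 150 bp)
compares foreground (TF-bound-class SNPs) against the non-bound-class
SNP windows as background — matched genomic background, not shuffled
sequence — with a two-sided exact binomial test of the core/flank split.

**Anchor choice.** Profiles are anchored on one *lead* SNP per enhancer
(the passing SNP with the smallest best P-value), the sentinel-SNP
convention of GWAS follow-up. Anchoring on every tagging SNP would count
a shared binding site once per co-located SNP and smear it across the
flanks of its neighbours' windows; at the compressed genome scale of the
synthetic study (where SNP spacing can fall below the +/-500 bp window)
this artifact is large, while at genomic SNP spacing it is negligible.
The generator plants correspondingly: one functional motif instance per
bound enhancer, near its lead SNP.

## Gene-set enrichment

The hypergeometric branch computes exact upper-tail probabilities as a
log-space sum of binomial coefficients and adjusts with
Benjamini-Hochberg across tested sets; the universe defaults to all
genes in the annotation and is configurable, because the universe used
by interactive enrichment portals is rarely recoverable. The GSEA branch
implements the weighted Kolmogorov-Smirnov running sum (hit increment
`|metric|^p` normalized over members, miss decrement `1/(N-K)`; the sum
ends at 0 by construction and this is asserted on every call), with ES
the extremum by absolute value and the leading edge on the extremum's
side. Significance uses gene-set permutation by default — size-matched
random member sets — because time-course designs with three replicates
admit only 20 distinct sample-label permutations, far too few for
1000-permutation P-values; phenotype (label-shuffling) mode is available
when replicate columns exist. NES divides ES by the mean |null ES| of
the same sign; the nominal P is the fraction of same-sign null ES at
least as extreme (so 1000 permutations can report P < 1/1000 as 0); FDR
follows the standard NES-pooling procedure. The ranking metric defaults
to signal-to-noise `(mu_a - mu_b)/(sd_a + sd_b)` with a floored
denominator, falling back to log2 fold change when a group has a single
sample.

## Tag matrices, clustering, superenhancers

`tag_density_matrix()` counts tag positions (strand-aware 5' ends by
default, midpoints optionally) in fixed-width bins over +/-3 kb windows
centered on peak centers. `centered_kmeans()` clusters row profiles
under `1 - Pearson` on mean-centered rows — the "centered" similarity of
classic expression-clustering tools — implemented as spherical K-means on
standardized rows so Lloyd updates provably never increase the
objective (asserted each iteration); 10 random restarts under a
mandatory seed make results reproducible; constant rows have correlation
0 with everything and fall to the lowest-index cluster, flagged.

Superenhancer calling follows the rank-signal geometry: peaks are
stitched when gaps are at most 12.5 kb (inclusive; optional removal of
peaks inside promoter windows first), per-region tag totals (optionally
minus depth-scaled control, floored at 0) are ranked, both axes are
scaled to the unit square, and the cutoff is the signal at the point
where a slope-1 line is tangent to the curve, found by brute-force
minimization of `y - x`. Ties on the minimum take the *last* index, so a
perfectly linear (degenerate) curve cuts at its top and calls nothing;
all-equal signals are flagged degenerate. Regions strictly above the
cutoff are superenhancers, an upward-closed suffix of the ranking.
Whether input subtraction is applied is a configuration choice, stated
in the output.

## Expression kinetics

Probesets collapse to gene symbols by keeping the probe with the highest
row mean (ties by probe id). Cross-species concordance is Pearson r
between the species' time profiles, retained at `r >= r_min` (default
0.5; "similar kinetics" has no canonical definition, so the threshold is
a stated parameter). Symbols match case-insensitively (mouse `Nfatc1`
vs human `NFATC1`), with an explicit ortholog map accepted. Retained
genes are clustered over the concatenated mouse + human course (4 + 4 =
8 samples by default; general lengths supported) with
`centered_kmeans()`; the cluster count for the time-course clustering is
a free parameter (default 4 in the demo, matching the size of the
kinetic shape library). Relative qPCR quantification is the textbook
`2^-ddCt` with a designated housekeeping gene.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions: a 2 x 1 Mb genome at GC 0.45
with 200 non-overlapping genes; ~1000 H3K27Ac regions of 400-1200 bp
placed off promoters, of which exactly 40% receive an embedded TF peak
(plus 300 TF-only peaks outside enhancers, so the Venn has all three
compartments); 10 000 SNPs drawn with 3x per-bp density inside bound
enhancers; spike-and-uniform P-values (15% associated SNPs draw
Beta(0.1, 1) in a random non-empty subset of the six groups, null SNPs
Uniform in all); one 10-bp purine-rich motif instance planted within
+/-75 bp of 80% of bound-class lead SNPs; a sequence-free tag landscape
(2 x 10 Mb) with 500 background peaks and 5 clustered high-signal loci
whose intra-locus gaps stay below the stitch distance, tag total exactly
equal to the configured depth; and 200 two-species 4-point expression
courses, 75 of them sharing a shape across species at noise sd 0.2, the
rest pairing non-positively-correlated shapes. Every generator is a pure
function of (config, seed); emission re-derives SNP class labels and
bound flags from the written files with independent `findInterval`
scans and aborts on any mismatch, and ground-truth gene lists come from
a brute-force nearest-TSS scan, not the production path.

Deliberately not modelled: linkage disequilibrium between SNPs (each SNP
is placed independently), chromatin-state segmentation beyond the
enhancer/promoter dichotomy, read-level sequencing noise (tags are
points, not alignments), probe-level microarray artifacts, and any
genome-build mismatch between inputs (the pipeline assumes a shared
build and says so; no liftover). Consequently, passing tests demonstrate
that the algorithms recover structure they are pointed at — not that the
pipeline is robust to LD-induced SNP clumping or to peak-calling
artifacts in real data.

## Numerical choices and degenerate inputs

* Interval intersection and merging delegate to `GenomicRanges` behind
  the package's 0-based surface; merge gaps are inclusive
  (`gap <= max_gap` merges).
* `hypergeometric_tail()` sums `lchoose` terms in log space and is
  validated against full subset enumeration for every configuration with
  a universe up to 12.
* Empty K-means clusters keep their previous centroid; restart selection
  takes the strictly better objective, so ties keep the earlier restart.
* Fisher tables with a zero cell report a Haldane-corrected (+0.5) odds
  ratio and a flag.
* Degenerate inputs follow the documented rules rather than erroring
  where a flagged answer is more useful: all-equal superenhancer
  signals, constant expression rows, `alpha = 1`, window 0, empty peak
  set in a gene-sharing comparison.

## Problem sizes used by the packaged checks

The test-suite and acceptance-script experiments run at the default
study conditions above, with these stated exceptions: the odds-ratio
recovery panel uses 20 000 SNPs, the Fisher null calibration uses 200
replicate panels of 8 000 SNPs on a 300-enhancer landscape, GSEA null
calibration uses 200 random 15-gene sets at 200 permutations on a
300-gene list (the planted-set check uses 1000 permutations on a
1000-gene list), and the demo pipeline configuration trims the landscape
to 600 enhancers / 4 000 SNPs. Each choice is a problem-size decision
for a desk-scale reproduction and is printed into the run manifest.

## Known limitations

* Nearest-TSS assignment is a heuristic for enhancer-target mapping;
  chromatin-contact data would be the stronger evidence and is out of
  scope.
* The motif scanner is exhaustive per window; it is meant for
  SNP-centered windows, not whole-genome scans.
* Gene-set permutation GSEA tests a different null than phenotype
  permutation (gene-label exchangeability rather than sample-label
  exchangeability); with adequate replicate counts the phenotype mode is
  preferable.
* The superenhancer cutoff inherits the known sensitivity of the
  rank-signal geometry to the signal dynamic range; the degenerate-curve
  flag marks the pathological cases but cannot make them informative.
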